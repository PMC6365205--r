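#' Thermal solver configuration
#'
#' @param dt solver time step, s.
#' @param heat_duration sonication (source-on) time, s.
#' @param total_duration simulated time, s (heating + cooling).
#' @param boundary "dirichlet" (constant temperature, rise pinned to 0 on the
#'   outer voxel layer) or "insulated" (zero flux; used by energy-balance
#'   diagnostics).
#' @param scheme "adi" (Douglas-Gunn alternating-direction implicit,
#'   unconditionally stable) or "explicit" (FTCS; errors if dt exceeds the
#'   stability bound).
#' @return An object of class \code{thermal_sim_config}.
#' @export
thermal_sim_config <- function(dt = 0.08, heat_duration = 18.16,
                               total_duration = 45.06,
                               boundary = c("dirichlet", "insulated"),
                               scheme = c("adi", "explicit")) {
  stopifnot(dt > 0, heat_duration <= total_duration)
  structure(list(dt = dt, heat_duration = heat_duration,
                 total_duration = total_duration,
                 boundary = match.arg(boundary),
                 scheme = match.arg(scheme)),
            class = "thermal_sim_config")
}

#' Temperature-rise field
#'
#' A 4-D record of temperature rise (deg C above baseline) over the grid at a
#' sequence of output frames, each frame the time average of the solver
#' states inside its window.
#'
#' @param grid a \code{voxel_grid}.
#' @param data numeric 4-D array (nx, ny, nz, n_frames).
#' @param times frame center times, s.
#' @param frame_duration window length of each frame, s (scalar or vector).
#' @return An object of class \code{temperature_field}.
#' @export
temperature_field <- function(grid, data, times, frame_duration) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == length(times))
  if (!identical(dim(data)[1:3], as.integer(grid$shape)))
    stop("temperature data dimensions do not match grid shape")
  structure(list(grid = grid, data = data, times = times,
                 frame_duration = frame_duration),
            class = "temperature_field")
}

#' @export
print.temperature_field <- function(x, ...) {
  cat(sprintf(
    "<temperature_field> %s voxels x %d frames (t = %.2f..%.2f s), max dT = %.3f C\n",
    paste(x$grid$shape, collapse = "x"), length(x$times), min(x$times),
    max(x$times), max(x$data)))
  invisible(x)
}

#' Solve the perfusionless Pennes bioheat equation
#'
#' Finite-difference solution of VHC dT/dt = div(kappa grad T) + Q on the
#' model grid with the power deposition active during the heating interval
#' and zero initial temperature rise. A 7-point stencil with harmonic-mean
#' face conductivities is used; the default stepping is Douglas-Gunn ADI.
#'
#' @param q a \code{q_field} (W/m^3) on the model grid.
#' @param model a \code{material_map} supplying kappa and VHC.
#' @param config a \code{thermal_sim_config}.
#' @param frame_duration output frame window, s; defaults to \code{config$dt}
#'   (every solver step is returned). Must be a multiple of dt and >= dt.
#' @param frame_steps advanced interface: explicit vector of per-frame step
#'   counts overriding \code{frame_duration} (used to align output frames to
#'   an acquisition raster with a trigger offset).
#' @param trace_voxel optional (i, j, k) voxel whose per-step temperature is
#'   returned as \code{trace}.
#' @param dense_k optional (k0, k1) slab bounds: the per-step temperature of
#'   slab slices k0..k1 is returned as a dense 4-D array \code{dense}.
#' @return A \code{temperature_field}; attributes \code{trace} and
#'   \code{dense} when requested.
#' @export
solve_pbhe <- function(q, model, config = thermal_sim_config(),
                       frame_duration = NULL, frame_steps = NULL,
                       trace_voxel = NULL, dense_k = NULL) {
  if (!same_grid(q$grid, model$grid))
    stop("Q and model grids do not match")
  grid <- model$grid
  dt <- config$dt
  if (is.null(frame_steps)) {
    if (is.null(frame_duration)) frame_duration <- dt
    if (frame_duration < dt - 1e-9)
      stop("frame_duration must be at least one time step")
    fs <- frame_duration / dt
    if (abs(fs - round(fs)) > 1e-6)
      stop("frame_duration must be a multiple of dt")
    n_steps <- round(config$total_duration / dt)
    nf <- floor(n_steps / round(fs))
    frame_steps <- rep(round(fs), nf)
  }
  n_steps <- sum(frame_steps)
  heat_steps <- round(config$heat_duration / dt)
  kappa <- property_volume(model, "kappa")
  vhc <- property_volume(model, "vhc")
  dx_m <- grid$spacing / 1000
  if (config$scheme == "explicit") {
    bound <- dx_m^2 * min(vhc) / (6 * max(kappa))
    if (dt > bound)
      stop(sprintf(
        "explicit FTCS unstable: dt = %g s exceeds the stability bound %.4g s; reduce dt or use scheme = 'adi'",
        dt, bound))
  }
  tr_idx <- -1L
  if (!is.null(trace_voxel))
    tr_idx <- as.integer((trace_voxel[1] - 1) +
                           grid$shape[1] * (trace_voxel[2] - 1) +
                           grid$shape[1] * grid$shape[2] * (trace_voxel[3] - 1))
  dk0 <- -1L; dk1 <- -1L
  if (!is.null(dense_k)) { dk0 <- dense_k[1] - 1L; dk1 <- dense_k[2] - 1L }
  res <- pbhe_run_cpp(numeric(prod(grid$shape)), as.vector(q$q),
                      as.vector(kappa), as.vector(vhc), grid$shape, dx_m, dt,
                      as.integer(frame_steps), heat_steps,
                      ifelse(config$scheme == "explicit", 0L, 1L),
                      ifelse(config$boundary == "dirichlet", 0L, 1L),
                      tr_idx, dk0, dk1)
  ends <- cumsum(frame_steps) * dt
  centers <- ends - frame_steps * dt / 2
  out <- temperature_field(grid, res$frames, centers, frame_steps * dt)
  if (tr_idx >= 0) attr(out, "trace") <- res$trace
  if (dk0 >= 0) attr(out, "dense") <- res$dense
  attr(out, "final") <- res$final
  out
}

# two-point linear interpolation weights of new voxel centers onto old ones
# (clamped at the ends); returns a sparse-ish weight matrix n_new x n_old
interp_weights <- function(old_centers, new_centers) {
  n_old <- length(old_centers)
  W <- matrix(0, length(new_centers), n_old)
  for (i in seq_along(new_centers)) {
    x <- new_centers[i]
    j <- findInterval(x, old_centers)
    if (j < 1) {
      W[i, 1] <- 1
    } else if (j >= n_old) {
      W[i, n_old] <- 1
    } else {
      w <- (x - old_centers[j]) / (old_centers[j + 1] - old_centers[j])
      W[i, j] <- 1 - w
      W[i, j + 1] <- w
    }
  }
  W
}

# separable trilinear resampling of a 3-D array between voxel grids
resample_trilinear <- function(arr, grid, target_spacing) {
  shp <- dim(arr)
  new_shape <- pmax(1L, as.integer(round(shp * grid$spacing / target_spacing)))
  new_grid <- voxel_grid(new_shape, target_spacing,
                         origin = grid$origin)
  out <- arr
  for (ax in 1:3) {
    W <- interp_weights(grid_coords(grid, ax),
                        grid_coords(new_grid, ax))
    d <- dim(out)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(out, perm)
    dm <- dim(m)
    m <- W %*% matrix(m, dm[1])
    dim(m) <- c(nrow(W), dm[2], dm[3])
    out <- aperm(m, order(perm))
  }
  list(arr = out, grid = new_grid)
}

#' Match a simulated temperature series to the MRTI raster
#'
#' Averages the temperature record over consecutive acquisition-length
#' windows and resamples it spatially (separable linear interpolation) to the
#' thermometry resolution.
#'
#' @param temps a \code{temperature_field} (typically at solver-step timing).
#' @param frame_duration acquisition frame length, s (default 3.36).
#' @param target_spacing target isotropic spacing, mm (default 0.5).
#' @return A \code{temperature_field} on the resampled grid with
#'   frame-averaged timing.
#' @export
match_mrti <- function(temps, frame_duration = 3.36, target_spacing = 0.5) {
  dt <- temps$frame_duration[1]
  if (frame_duration < dt - 1e-9)
    stop("frame_duration must be at least the series time spacing")
  fs <- round(frame_duration / dt)
  if (abs(frame_duration / dt - fs) > 1e-6)
    stop("frame_duration must be a multiple of the series time spacing")
  nt <- dim(temps$data)[4]
  nf <- floor(nt / fs)
  shp <- dim(temps$data)[1:3]
  resamp_needed <- abs(temps$grid$spacing - target_spacing) > 1e-9
  frames <- NULL
  times <- numeric(nf)
  for (f in seq_len(nf)) {
    idx <- ((f - 1) * fs + 1):(f * fs)
    m <- temps$data[, , , idx, drop = FALSE]
    dim(m) <- c(prod(shp), length(idx))
    avg <- array(rowMeans(m), dim = shp)
    if (resamp_needed) {
      rs <- resample_trilinear(avg, temps$grid, target_spacing)
      avg <- rs$arr
      new_grid <- rs$grid
    } else new_grid <- temps$grid
    if (is.null(frames))
      frames <- array(0, dim = c(dim(avg), nf))
    frames[, , , f] <- avg
    times[f] <- mean(temps$times[idx])
  }
  temperature_field(new_grid, frames, times, frame_duration)
}
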