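#' Synthetic MR thermometry series
#'
#' Container for emulated MRTI measurements: a replicate stack of framed,
#' resampled, noisy, drifted temperature volumes on the reconstruction grid.
#'
#' @name mrti_series
#' @details Fields: \code{data} (nx, ny, nz, n_frames, n_replicates),
#' \code{grid} (reconstruction grid, 0.5 mm isotropic by default),
#' \code{times} (frame centers, acquisition time, s), \code{frame_duration},
#' \code{trigger_delay} (heating starts this long after acquisition starts),
#' \code{native_spacing} (acquisition voxel size, mm), \code{noise_sigma},
#' \code{drift_rate}, \code{seed}, and \code{truth} (the noiseless chain
#' output, kept for reference-region checks).
NULL

#' Replicate-averaged MRTI data
#'
#' @param series an \code{mrti_series}.
#' @return 4-D array (space x frames) averaged over replicates.
#' @export
mrti_average <- function(series) {
  d <- dim(series$data)
  a <- series$data
  dim(a) <- c(prod(d[1:4]), d[5])
  out <- rowMeans(a)
  dim(out) <- d[1:4]
  out
}

#' @export
print.mrti_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("<mrti_series> %d x %d x %d voxels x %d frames x %d ",
                     "replicate(s), sigma = %.3g C, drift = %.4g C/s\n"),
              d[1], d[2], d[3], d[4], d[5], x$noise_sigma, x$drift_rate))
  invisible(x)
}

# block (box) average along each axis by integer factors, cropping trailing
# samples that do not fill a block
box_average <- function(arr, factors) {
  d <- dim(arr)
  keep <- (d %/% factors) * factors
  arr <- arr[seq_len(keep[1]), seq_len(keep[2]), seq_len(keep[3]),
             drop = FALSE]
  for (ax in 1:3) {
    f <- factors[ax]
    if (f == 1L) next
    d <- dim(arr)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    m <- matrix(m, f)
    m <- colMeans(m)
    dim(m) <- c(dm[1] / f, dm[2], dm[3])
    arr <- aperm(m, order(perm))
  }
  arr
}

# 1-D Fourier zero-fill interpolation along the first dimension of a matrix
fourier_upsample_mat <- function(m, factor) {
  n <- nrow(m)
  N <- n * factor
  X <- stats::mvfft(m)
  out <- matrix(complex(real = 0), N, ncol(m))
  h <- ceiling(n / 2)
  out[seq_len(h), ] <- X[seq_len(h), ]
  if (n > 1) {
    lo <- (h + 1):n
    out[N - n + lo, ] <- X[lo, ]
    if (n %% 2 == 0) { # split the Nyquist bin
      out[h + 1, ] <- X[h + 1, ] / 2
      out[N - n + h + 1, ] <- X[h + 1, ] / 2
    }
  }
  Re(stats::mvfft(out, inverse = TRUE)) / n
}

# zero-fill (Fourier) interpolation of a 3-D array by integer factors
fourier_upsample <- function(arr, factors) {
  for (ax in 1:3) {
    f <- factors[ax]
    if (f == 1L) next
    d <- dim(arr)
    perm <- c(ax, setdiff(1:3, ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    m <- fourier_upsample_mat(matrix(m, dm[1]), f)
    dim(m) <- c(dm[1] * f, dm[2], dm[3])
    arr <- aperm(m, order(perm))
  }
  arr
}

#' Emulate the MRTI measurement chain
#'
#' Turns a noiseless simulated temperature record into a synthetic
#' experimental measurement: the truth is shifted by the acquisition trigger
#' delay, box-averaged to the native acquisition voxel size, averaged over
#' acquisition-length frames, zero-fill (Fourier) interpolated to the
#' reconstruction resolution, and then per-replicate white Gaussian noise
#' and a linear temporal drift are added. Deterministic for a given seed.
#'
#' @param truth a \code{temperature_field} sampled at the solver time step
#'   (frame_duration = dt), simulation time starting at heat-on.
#' @param noise_sigma per-replicate temperature noise, deg C (>= 0).
#' @param drift_rate linear drift, deg C per second (default -0.007).
#' @param trigger_delay heating start relative to acquisition start, s.
#' @param replicates number of replicate sonications emulated.
#' @param seed RNG seed.
#' @param native_spacing acquisition voxel size (x, y, z), mm.
#' @param out_spacing reconstruction spacing, mm.
#' @param frame_duration acquisition frame length, s.
#' @param wpcs_scale thermometry-coefficient miscalibration factor: measured
#'   temperatures are scaled by this before noise is added (1 = calibrated).
#' @param interp "fourier" (zero-fill) or "linear" (trilinear) resampling.
#' @return An \code{mrti_series}.
#' @export
synthesize_mrti <- function(truth, noise_sigma, drift_rate = -0.007,
                            trigger_delay = 2.0, replicates = 3, seed = 1,
                            native_spacing = c(1, 1, 3), out_spacing = 0.5,
                            frame_duration = 3.36, wpcs_scale = 1,
                            interp = c("fourier", "linear")) {
  interp <- match.arg(interp)
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  dt <- truth$frame_duration[1]
  fs <- round(frame_duration / dt)
  ds <- round(trigger_delay / dt)
  if (abs(frame_duration / dt - fs) > 1e-6 ||
      abs(trigger_delay / dt - ds) > 1e-6)
    stop("frame_duration and trigger_delay must be multiples of the truth time step")
  nt <- dim(truth$data)[4]
  n_frames <- (nt + ds) %/% fs
  if (n_frames < 1) stop("truth does not cover one acquisition frame")

  # spatial factors truth -> native
  f_nat <- native_spacing / truth$grid$spacing
  if (any(abs(f_nat - round(f_nat)) > 1e-6))
    stop("native_spacing must be integer multiples of the truth spacing")
  f_nat <- as.integer(round(f_nat))
  f_out <- native_spacing / out_spacing
  if (any(abs(f_out - round(f_out)) > 1e-6))
    stop("native_spacing must be integer multiples of out_spacing")
  f_out <- as.integer(round(f_out))

  shp <- dim(truth$data)[1:3]
  nat_shape <- shp %/% f_nat
  out_shape <- nat_shape * f_out
  # reconstruction grid: sample positions of the zero-fill interpolation
  out_origin <- truth$grid$origin +
    (f_nat * truth$grid$spacing) / 2 - out_spacing / 2
  out_grid <- voxel_grid(out_shape, out_spacing, origin = out_origin)

  frames <- array(0, dim = c(out_shape, n_frames))
  times <- numeric(n_frames)
  for (f in seq_len(n_frames)) {
    # acquisition window in simulation steps (zero before heat-on trigger)
    s0 <- (f - 1) * fs - ds + 1
    s1 <- f * fs - ds
    idx <- seq(max(s0, 1), s1)
    if (s1 < 1) {
      avg_nat <- array(0, dim = nat_shape)
    } else {
      m <- truth$data[, , , idx, drop = FALSE]
      dim(m) <- c(prod(shp), length(idx))
      avg <- array(rowSums(m) / fs, dim = shp)  # pre-trigger steps are zero
      avg_nat <- box_average(avg, f_nat)
    }
    up <- if (all(f_out == 1L)) avg_nat
          else if (interp == "fourier") fourier_upsample(avg_nat, f_out)
          else {
            nat_grid <- voxel_grid(nat_shape, native_spacing[1],
                                   origin = truth$grid$origin)
            # anisotropic native voxels: interpolate axis by axis
            res <- avg_nat
            for (ax in 1:3) {
              if (f_out[ax] == 1L) next
              old <- truth$grid$origin[ax] +
                (seq_len(nat_shape[ax]) - 0.5) * native_spacing[ax]
              new <- out_origin[ax] + (seq_len(out_shape[ax]) - 0.5) * out_spacing
              W <- interp_weights(old, new)
              d <- dim(res)
              perm <- c(ax, setdiff(1:3, ax))
              mm <- aperm(res, perm)
              dmm <- dim(mm)
              mm <- W %*% matrix(mm, dmm[1])
              dim(mm) <- c(nrow(W), dmm[2], dmm[3])
              res <- aperm(mm, order(perm))
            }
            res
          }
    frames[, , , f] <- up
    times[f] <- (f - 0.5) * frame_duration
  }

  set.seed(seed)
  data <- array(0, dim = c(out_shape, n_frames, replicates))
  for (r in seq_len(replicates)) {
    noise <- array(stats::rnorm(prod(out_shape) * n_frames, 0, noise_sigma),
                   dim = c(out_shape, n_frames))
    drift <- rep(drift_rate * times, each = prod(out_shape))
    data[, , , , r] <- wpcs_scale * frames + noise + drift
  }
  structure(list(grid = out_grid, data = data, times = times,
                 frame_duration = frame_duration,
                 trigger_delay = trigger_delay,
                 native_spacing = native_spacing,
                 noise_sigma = noise_sigma, drift_rate = drift_rate,
                 replicates = replicates, seed = seed, truth = frames),
            class = "mrti_series")
}

#' Default non-heated reference region
#'
#' Picks a compact 36-voxel block in the central z slice, as far from the
#' beam axis as the grid allows (at least 20 mm transverse when available).
#'
#' @param series an \code{mrti_series}.
#' @param n number of voxels (default 36).
#' @return Integer matrix (n x 3) of voxel indices.
#' @export
default_reference_region <- function(series, n = 36) {
  grid <- series$grid
  x <- grid_coords(grid, 1)
  kz <- ceiling(grid$shape[3] / 2)
  want_cols <- 6
  want_rows <- ceiling(n / want_cols)
  xi <- order(x, decreasing = TRUE)[seq_len(want_rows)]
  y <- grid_coords(grid, 2)
  yi <- order(abs(y))[seq_len(want_cols)]
  reg <- as.matrix(expand.grid(i = sort(xi), j = sort(yi), k = kz))
  reg[seq_len(n), , drop = FALSE]
}

region_series <- function(data4, region) {
  nt <- dim(data4)[4]
  vapply(seq_len(nt), function(f) {
    mean(data4[cbind(region, f)])
  }, numeric(1))
}

#' Remove linear temporal drift using a non-heated reference region
#'
#' Fits a line to the mean reference-region temperature versus time for each
#' replicate and subtracts the fitted line voxel-wise.
#'
#' @param series an \code{mrti_series}.
#' @param reference_region integer matrix (n x 3) of voxel indices; default
#'   \code{\link{default_reference_region}}.
#' @param heated_threshold reference voxels whose noiseless (truth)
#'   temperature exceeds this are considered heated, deg C.
#' @return The corrected \code{mrti_series}.
#' @export
correct_drift <- function(series, reference_region = NULL,
                          heated_threshold = 0.1) {
  if (is.null(reference_region))
    reference_region <- default_reference_region(series)
  if (!is.null(series$truth)) {
    tmax <- max(vapply(seq_len(dim(series$truth)[4]), function(f)
      max(series$truth[cbind(reference_region, f)]), numeric(1)))
    if (tmax > heated_threshold)
      warning("reference region overlaps heating (truth rise ",
              sprintf("%.2f C); drift estimate may be biased", tmax))
  }
  for (r in seq_len(dim(series$data)[5])) {
    rep_data <- mrti_replicate(series, r)
    ref <- region_series(rep_data, reference_region)
    fit <- stats::lm(ref ~ series$times)
    line <- stats::fitted(fit)
    series$data[, , , , r] <- rep_data -
      rep(line, each = prod(series$grid$shape))
  }
  series
}

# one replicate as a 4-D array (singleton spatial dimensions preserved)
mrti_replicate <- function(series, r) {
  out <- series$data[, , , , r, drop = FALSE]
  dim(out) <- dim(series$data)[1:4]
  out
}

#' Signal-to-noise ratio of an MRTI series
#'
#' The noise sigma is the per-voxel temporal standard deviation averaged over
#' the reference region of the replicate-averaged series; SNR is the
#' spatiotemporal peak divided by sigma.
#'
#' @param series an \code{mrti_series}.
#' @param reference_region integer matrix (n x 3); default a 36-voxel
#'   non-heated block.
#' @return List with \code{snr}, \code{sigma}, \code{peak}, \code{region}.
#' @export
compute_snr <- function(series, reference_region = NULL) {
  if (is.null(reference_region))
    reference_region <- default_reference_region(series)
  if (!nrow(reference_region)) stop("empty reference region")
  avg <- mrti_average(series)
  if (dim(avg)[4] < 2) stop("at least two frames are required")
  sds <- apply(reference_region, 1, function(v)
    stats::sd(avg[v[1], v[2], v[3], ]))
  sigma <- mean(sds)
  if (sigma == 0) stop("zero temporal noise in the reference region; SNR undefined")
  peak <- max(avg)
  list(snr = peak / sigma, sigma = sigma, peak = peak,
       region = reference_region)
}
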