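#' Complex steady-state pressure field
#'
#' @param grid a \code{voxel_grid}.
#' @param p complex array of grid shape, Pa.
#' @param frequency Hz.
#' @param reflected list of first-order reflected planes recorded at material
#'   interfaces (each a list with the slice index \code{k}, the face position,
#'   and the complex reflected plane).
#' @return An object of class \code{pressure_field}.
#' @export
pressure_field <- function(grid, p, frequency, reflected = list()) {
  check_grid_array(grid, p, "pressure")
  if (any(!is.finite(Re(p))) || any(!is.finite(Im(p))))
    stop("pressure field contains non-finite values")
  structure(list(grid = grid, p = p, frequency = frequency,
                 reflected = reflected),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("<pressure_field> %s voxels @ %g kHz, max |p| = %.3g Pa\n",
              paste(x$grid$shape, collapse = "x"), x$frequency / 1000,
              max(Mod(x$p))))
  invisible(x)
}

# Angular-spectrum diffraction of one transverse plane over dz_m using
# background wavenumber k0 (rad/m). Evanescent components are zeroed; the
# plane is zero-padded to a fast FFT size to suppress wrap-around.
diffract_plane <- function(p, dz_m, k0, pad) {
  Nx <- pad$Nx; Ny <- pad$Ny
  buf <- matrix(complex(real = 0), Nx, Ny)
  buf[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  kz2 <- k0^2 - pad$k2
  kz <- sqrt(pmax(kz2, 0))
  H <- matrix(exp(1i * kz * dz_m), Nx, Ny)
  H[kz2 <= 0] <- 0
  out <- stats::fft(stats::fft(buf) * H, inverse = TRUE) / (Nx * Ny)
  out[seq_len(nrow(p)), seq_len(ncol(p))]
}

# precompute padded FFT-plane metadata for a transverse grid
pad_plane <- function(nx, ny, dx_m, pad_voxels = 32) {
  Nx <- stats::nextn(nx + 2 * pad_voxels, c(2, 3, 5))
  Ny <- stats::nextn(ny + 2 * pad_voxels, c(2, 3, 5))
  fft_freq <- function(n, d) {
    f <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / (n * d)
    2 * pi * f
  }
  kx <- fft_freq(Nx, dx_m)
  ky <- fft_freq(Ny, dx_m)
  list(Nx = Nx, Ny = Ny, k2 = outer(kx^2, ky^2, "+"))
}

#' Hybrid angular spectrum propagation through a voxel model
#'
#' Marches the initial plane pressure through the model slice by slice along
#' z. Each step applies (a) an angular-spectrum diffraction transfer function
#' in the spatial-frequency domain using the slice's background sound speed
#' and (b) a per-voxel space-domain correction for sound-speed deviations
#' (refraction) and attenuation decay exp(-alpha(f) dz), with
#' alpha(f) = alpha0 (f/1MHz)^freq_exponent. Where the material changes
#' between slices, the transmitted amplitude is scaled by the
#' normal-incidence pressure transmission coefficient and the first-order
#' reflected plane is recorded (it is not re-propagated forward). The first
#' step spans half a voxel so stored planes sample slice centers.
#'
#' @param initial_plane complex matrix (nx x ny), the pressure in water at
#'   the proximal model face.
#' @param model a \code{material_map}.
#' @param frequency drive frequency, Hz.
#' @param pad_voxels zero-padding width for the FFT (>= 32 recommended).
#' @return A \code{pressure_field}.
#' @export
has_propagate <- function(initial_plane, model, frequency, pad_voxels = 32) {
  grid <- model$grid
  if (!identical(dim(initial_plane), grid$shape[1:2]))
    stop("initial plane dimensions do not match the model's transverse grid")
  sos_vals <- vapply(model$palette, `[[`, numeric(1), "sos")
  if (any(sos_vals <= 0)) stop("zero or negative sound speed in palette")
  rho_vals <- vapply(model$palette, `[[`, numeric(1), "rho")
  alpha_vals <- vapply(model$palette, function(m)
    attenuation_at(m, frequency), numeric(1))
  Z_vals <- rho_vals * sos_vals
  omega <- 2 * pi * frequency
  dx_m <- grid$spacing / 1000
  pad <- pad_plane(grid$shape[1], grid$shape[2], dx_m, pad_voxels)

  p <- array(complex(real = 0), dim = grid$shape)
  cur <- initial_plane
  prev_lab <- matrix(1L, grid$shape[1], grid$shape[2])  # water at entry
  reflected <- list()
  for (k in seq_len(grid$shape[3])) {
    lab <- model$labels[, , k]
    changed <- lab != prev_lab
    if (any(changed)) {
      Z1 <- matrix(Z_vals[prev_lab], nrow(lab), ncol(lab))
      Z2 <- matrix(Z_vals[lab], nrow(lab), ncol(lab))
      refl <- matrix(complex(real = 0), nrow(lab), ncol(lab))
      refl[changed] <- cur[changed] *
        ((Z2 - Z1) / (Z2 + Z1))[changed]
      reflected[[length(reflected) + 1L]] <-
        list(k = k, plane = refl)
      tcoef <- matrix(1, nrow(lab), ncol(lab))
      tcoef[changed] <- (2 * Z2 / (Z2 + Z1))[changed]
      cur <- cur * tcoef
    }
    dz_m <- if (k == 1L) dx_m / 2 else dx_m
    c_bg <- mean(sos_vals[lab])
    k0 <- omega / c_bg
    cur <- diffract_plane(cur, dz_m, k0, pad)
    kv <- omega / sos_vals[lab]
    av <- alpha_vals[lab]
    cur <- cur * exp((1i * (kv - k0) - av) * dz_m)
    p[, , k] <- cur
    prev_lab <- lab
  }
  pressure_field(grid, p, frequency, reflected)
}

#' Power deposition field
#'
#' @param grid a \code{voxel_grid}.
#' @param q numeric array of grid shape, W/m^3, all >= 0.
#' @return An object of class \code{q_field}.
#' @export
q_field <- function(grid, q) {
  check_grid_array(grid, q, "Q")
  if (any(q < 0)) stop("Q must be non-negative")
  structure(list(grid = grid, q = q), class = "q_field")
}

#' @export
print.q_field <- function(x, ...) {
  cat(sprintf("<q_field> %s voxels, max Q = %.4g W/m^3\n",
              paste(x$grid$shape, collapse = "x"), max(x$q)))
  invisible(x)
}

#' Power deposition from a pressure field
#'
#' Q = alpha_a(f) |p|^2 / (rho c), the plane-wave relation Q = 2 alpha_a I
#' with I = |p|^2 / (2 rho c). The absorption coefficient is taken equal to
#' the attenuation coefficient (negligible scattering). Water voxels
#' (alpha = 0) deposit nothing. First-order reflected planes recorded during
#' propagation can optionally be back-propagated in a single pass and added
#' to the deposition; by default they are excluded (their intensity fraction
#' is R^2, below a percent for these media).
#'
#' @param pressure a \code{pressure_field}.
#' @param model the \code{material_map} used for propagation.
#' @param include_reflections if TRUE, deposit the one-pass backward
#'   reflected wave as well.
#' @param pad_voxels FFT padding for the backward pass.
#' @return A \code{q_field} in W/m^3.
#' @export
compute_q <- function(pressure, model, include_reflections = FALSE,
                      pad_voxels = 32) {
  if (!same_grid(pressure$grid, model$grid))
    stop("pressure and model grids do not match")
  alpha_vals <- vapply(model$palette, function(m)
    attenuation_at(m, pressure$frequency), numeric(1))
  sos_vals <- vapply(model$palette, `[[`, numeric(1), "sos")
  rho_vals <- vapply(model$palette, `[[`, numeric(1), "rho")
  av <- array(alpha_vals[model$labels], dim = model$grid$shape)
  rc <- array((rho_vals * sos_vals)[model$labels], dim = model$grid$shape)
  q <- av * Mod(pressure$p)^2 / rc
  if (include_reflections && length(pressure$reflected)) {
    grid <- model$grid
    omega <- 2 * pi * pressure$frequency
    dx_m <- grid$spacing / 1000
    pad <- pad_plane(grid$shape[1], grid$shape[2], dx_m, pad_voxels)
    by_k <- integer(0)
    for (r in pressure$reflected) by_k <- c(by_k, r$k)
    kmax <- max(by_k)
    cur <- matrix(complex(real = 0), grid$shape[1], grid$shape[2])
    for (k in seq(kmax, 1)) {
      for (r in pressure$reflected)
        if (r$k == k) cur <- cur + r$plane
      lab <- model$labels[, , k]
      c_bg <- mean(sos_vals[lab])
      cur <- diffract_plane(cur, dx_m, omega / c_bg, pad)
      kv <- omega / sos_vals[lab]
      avk <- alpha_vals[lab]
      cur <- cur * exp((1i * (kv - omega / c_bg) - avk) * dx_m)
      q[, , k] <- q[, , k] + avk * Mod(cur)^2 / (rho_vals * sos_vals)[lab]
    }
  }
  q_field(model$grid, q)
}

# plane-integrated forward power at each z slice (W); diagnostic used by the
# free-space unitarity checks
plane_power <- function(pressure, model) {
  sos_vals <- vapply(model$palette, `[[`, numeric(1), "sos")
  rho_vals <- vapply(model$palette, `[[`, numeric(1), "rho")
  dA <- (model$grid$spacing / 1000)^2
  vapply(seq_len(model$grid$shape[3]), function(k) {
    lab <- model$labels[, , k]
    rc <- (rho_vals * sos_vals)[lab]
    sum(Mod(pressure$p[, , k])^2 / (2 * rc)) * dA
  }, numeric(1))
}
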