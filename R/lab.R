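#' Power-law fit of attenuation versus frequency
#'
#' Fits alpha(f) = alpha0 * f^c to through-transmission attenuation
#' measurements by least squares in log-log space (the model is a power
#' law); a nonlinear fit in linear space is available as an alternative
#' mode. alpha0 is the attenuation at 1 MHz.
#'
#' @param freqs_mhz measurement center frequencies, MHz (> 0, >= 2 distinct).
#' @param alphas_np_cm measured pressure attenuation, Np/cm (> 0).
#' @param space "log" (default) or "linear" fitting space.
#' @return An object of class \code{attenuation_fit}: \code{alpha0} (Np/cm at
#'   1 MHz), \code{freq_exponent}, fitted values and residuals.
#' @export
fit_attenuation_powerlaw <- function(freqs_mhz, alphas_np_cm,
                                     space = c("log", "linear")) {
  space <- match.arg(space)
  if (any(freqs_mhz <= 0) || any(alphas_np_cm <= 0))
    stop("frequencies and attenuations must be positive")
  if (length(unique(freqs_mhz)) < 2)
    stop("at least two distinct frequencies are required")
  logfit <- stats::lm(log(alphas_np_cm) ~ log(freqs_mhz))
  alpha0 <- exp(stats::coef(logfit)[[1]])
  cexp <- stats::coef(logfit)[[2]]
  if (space == "linear") {
    # direct least squares in linear space, started from the log-log fit
    # (robust to exact-fit data, unlike nls)
    obj <- function(p) sum((exp(p[1]) * freqs_mhz^p[2] - alphas_np_cm)^2)
    o <- stats::optim(c(log(alpha0), cexp), obj,
                      control = list(reltol = 1e-15, maxit = 5000))
    alpha0 <- exp(o$par[1])
    cexp <- o$par[2]
  }
  fitted <- alpha0 * freqs_mhz^cexp
  structure(list(alpha0 = alpha0, freq_exponent = cexp,
                 freqs_mhz = freqs_mhz, alphas_np_cm = alphas_np_cm,
                 fitted = fitted, residuals = alphas_np_cm - fitted),
            class = "attenuation_fit")
}

#' @export
print.attenuation_fit <- function(x, ...) {
  cat(sprintf("<attenuation_fit> alpha0 = %.4g Np/cm @ 1 MHz, exponent = %.3f\n",
              x$alpha0, x$freq_exponent))
  invisible(x)
}

#' Absorbed acoustic power from a radiation force balance reading
#'
#' P_abs = c g m / k, with c the speed of sound in water (1500 m/s), g the
#' gravitational acceleration (9.8 m/s^2), m the mean balance mass reading
#' (kg), and k the cone-angle correction for the spread of ray angles from a
#' focused source (0.919 by default).
#'
#' @param m_kg mean balance mass reading, kg (>= 0).
#' @param k cone-angle correction factor, in (0, 1].
#' @param c_water speed of sound in water, m/s.
#' @param g gravitational acceleration, m/s^2.
#' @return Absorbed power, W.
#' @export
absorbed_power <- function(m_kg, k = 0.919, c_water = 1500, g = 9.8) {
  if (any(m_kg < 0)) stop("balance mass must be non-negative")
  stopifnot(k > 0, k <= 1)
  c_water * g * m_kg / k
}

#' Attenuation from an insertion-loss (substitution) power measurement
#'
#' alpha = ln(P_r / P_s) / (2 d_e): the power ratio with and without the
#' sample in the beam path over twice the effective (angular-spread
#' corrected) path length. Reported positive for a lossy sample.
#'
#' @param p_sample_W measured power with the sample in place, W (> 0).
#' @param p_reference_W measured power with the water reference, W (> 0).
#' @param d_e_cm effective beam path length through the sample, cm
#'   (default 3.2).
#' @return Attenuation in Np/cm (negative if the sample reads hotter than
#'   the reference).
#' @export
insertion_loss_attenuation <- function(p_sample_W, p_reference_W,
                                       d_e_cm = 3.2) {
  if (any(c(p_sample_W, p_reference_W, d_e_cm) <= 0))
    stop("powers and path length must be positive")
  log(p_reference_W / p_sample_W) / (2 * d_e_cm)
}

#' Normal-incidence reflection coefficients between two media
#'
#' Pressure coefficient R = (Z2 - Z1) / (Z2 + Z1) with Z = rho c, and the
#' intensity coefficient R^2.
#'
#' @param medium1,medium2 \code{medium_properties} of the incident and
#'   transmitting media.
#' @return List with \code{pressure} (signed R) and \code{intensity} (R^2).
#' @export
reflection_coefficients <- function(medium1, medium2) {
  Z1 <- medium1$rho * medium1$sos
  Z2 <- medium2$rho * medium2$sos
  R <- (Z2 - Z1) / (Z2 + Z1)
  list(pressure = R, intensity = R^2)
}

#' Transducer electroacoustic efficiency
#'
#' @param acoustic_W measured acoustic output power, W.
#' @param electrical_W applied electrical power, W (> 0).
#' @return Efficiency fraction.
#' @export
transducer_efficiency <- function(acoustic_W, electrical_W) {
  if (any(electrical_W <= 0)) stop("electrical power must be positive")
  acoustic_W / electrical_W
}
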