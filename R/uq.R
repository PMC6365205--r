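#' Parameter distribution for uncertainty propagation
#'
#' @param name parameter name.
#' @param mean distribution mean (SI units).
#' @param sd standard deviation (>= 0, same units).
#' @param group optional group id; parameters sharing a group are sampled
#'   from a joint normal with the group's correlation.
#' @return An object of class \code{parameter_distribution}.
#' @export
param_dist <- function(name, mean, sd, group = NULL) {
  stopifnot(sd >= 0)
  structure(list(name = name, mean = mean, sd = sd, group = group),
            class = "parameter_distribution")
}

#' Sample input parameters
#'
#' Draws n joint samples of the input parameters: independent normals for
#' ungrouped parameters and a joint normal (with the stated correlation) for
#' each group. Non-physical negative draws of non-negative quantities are
#' resampled (truncation at zero); at the uncertainty levels in use this is
#' vanishingly rare. Reproducible for a given seed, and the marginal draws
#' of each parameter do not depend on the other parameters' standard
#' deviations (so one-at-a-time designs reuse identical draws).
#'
#' @param dists list of \code{parameter_distribution}.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param group_correlation named list of correlations (scalar, for 2-member
#'   groups) keyed by group id; defaults to 0.
#' @param truncate_at_zero resample negative draws (default TRUE).
#' @return Numeric matrix n x k with parameter names as columns.
#' @export
sample_parameters <- function(dists, n, seed, group_correlation = list(),
                              truncate_at_zero = TRUE) {
  stopifnot(n >= 1)
  k <- length(dists)
  nms <- vapply(dists, `[[`, character(1), "name")
  means <- vapply(dists, `[[`, numeric(1), "mean")
  sds <- vapply(dists, `[[`, numeric(1), "sd")
  groups <- lapply(dists, `[[`, "group")
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * k), n, k)
  X <- matrix(rep(means, each = n), n, k)
  colnames(X) <- nms
  # correlate grouped columns (Cholesky of the correlation matrix)
  gids <- unique(unlist(groups))
  for (g in gids) {
    idx <- which(vapply(groups, identical, logical(1), g))
    if (length(idx) < 2) next
    rho <- group_correlation[[g]] %||% 0
    R <- diag(length(idx))
    R[upper.tri(R)] <- rho
    R[lower.tri(R)] <- rho
    L <- tryCatch(chol(R), error = function(e)
      stop("group '", g, "' correlation matrix is not positive definite"))
    Z[, idx] <- Z[, idx, drop = FALSE] %*% L
  }
  for (j in seq_len(k)) X[, j] <- means[j] + sds[j] * Z[, j]
  if (truncate_at_zero) {
    for (j in seq_len(k)) {
      if (sds[j] == 0 || means[j] < 0) next
      bad <- which(X[, j] < 0)
      guard <- 0L
      while (length(bad) && guard < 100L) {
        X[bad, j] <- means[j] + sds[j] * stats::rnorm(length(bad))
        bad <- which(X[, j] < 0)
        guard <- guard + 1L
      }
    }
  }
  X
}

#' Input distributions for a phantom sonication scenario
#'
#' The six uncertain simulation inputs: acoustic attenuation, speed of
#' sound, acoustic power, density (independent normals), and thermal
#' conductivity with volumetric heat capacity (joint normal group
#' "thermal", correlation configurable; they are measured by the same
#' probe and not independently).
#'
#' @param milk_fraction phantom composition (10, 30, 50, 70 percent milk).
#' @param power_W mean acoustic power, W.
#' @return List of \code{parameter_distribution} (alpha0, sos, power, rho,
#'   kappa, vhc). alpha0 in Np/m at 1 MHz; the rest SI.
#' @export
scenario_distributions <- function(milk_fraction, power_W) {
  p <- phantom_properties(milk_fraction)
  u <- phantom_uncertainties(milk_fraction)
  list(param_dist("alpha0", p$alpha0, u[["alpha0"]] * p$alpha0),
       param_dist("sos", p$sos, u[["sos"]] * p$sos),
       param_dist("power", power_W, u[["power"]] * power_W),
       param_dist("rho", p$rho, u[["rho"]] * p$rho),
       param_dist("kappa", p$kappa, u[["kappa"]] * p$kappa, group = "thermal"),
       param_dist("vhc", p$vhc, u[["vhc"]] * p$vhc, group = "thermal"))
}

#' Expected experimental variability from SNR
#'
#' epsilon = 100 / SNR, the percent measurement variability implied by the
#' thermometry signal-to-noise ratio.
#'
#' @param snr signal-to-noise ratio (> 0).
#' @return epsilon in percent.
#' @export
epsilon_from_snr <- function(snr) {
  if (any(snr <= 0)) stop("SNR must be positive")
  100 / snr
}

#' Monte Carlo sample size for a target precision
#'
#' n = round((1.96 * 100 * sigma_sub / (epsilon * ybar_sub))^2): the number
#' of iterations for the 95 percent confidence half-width of the output mean
#' to fall below the expected experimental variability epsilon (percent),
#' given a pilot subsample's output mean and standard deviation.
#'
#' @param sigma_sub pilot-subsample standard deviation of the output.
#' @param ybar_sub pilot-subsample mean of the output (nonzero).
#' @param epsilon expected experimental variability, percent (> 0).
#' @return Required iterations (integer, floored at 1).
#' @export
required_iterations <- function(sigma_sub, ybar_sub, epsilon) {
  if (ybar_sub == 0) stop("pilot mean is zero")
  stopifnot(epsilon > 0, sigma_sub >= 0)
  max(1L, as.integer(round((1.96 * 100 * sigma_sub / (epsilon * ybar_sub))^2)))
}

#' Monte Carlo uncertainty propagation
#'
#' Runs \code{model} on n parameter samples and summarizes per-metric means,
#' standard deviations and percent uncertainties U = 100 sd / mean. The
#' model is any function taking a named parameter vector and returning
#' either a named numeric vector of output metrics, or a list with elements
#' \code{metrics} (named numeric) and optionally \code{trace} (a per-frame
#' temperature curve, pooled into the time-resolved envelope).
#'
#' @param model evaluation function (see Details).
#' @param dists list of \code{parameter_distribution}.
#' @param n iterations (>= 1).
#' @param seed RNG seed; sampling is reproducible per seed.
#' @param group_correlation see \code{\link{sample_parameters}}.
#' @param trace_times optional frame times attached to the envelope.
#' @return An object of class \code{mc_result}: \code{X} (samples),
#'   \code{Y} (metrics matrix), \code{summary} (mean, sd, U per metric),
#'   and \code{envelope} (per-frame mean/sd of the traced curve) when the
#'   model returns traces.
#' @export
run_mc <- function(model, dists, n, seed, group_correlation = list(),
                   trace_times = NULL) {
  X <- sample_parameters(dists, n, seed, group_correlation)
  Y <- NULL
  traces <- NULL
  for (i in seq_len(n)) {
    res <- tryCatch(model(X[i, ]), error = function(e)
      stop("model evaluation failed at iteration ", i, " (",
           paste(sprintf("%s=%.5g", colnames(X), X[i, ]), collapse = ", "),
           "): ", conditionMessage(e)))
    metrics <- if (is.list(res)) res$metrics else res
    if (is.null(Y)) Y <- matrix(NA_real_, n, length(metrics),
                                dimnames = list(NULL, names(metrics)))
    Y[i, ] <- metrics
    if (is.list(res) && !is.null(res$trace)) {
      if (is.null(traces)) traces <- matrix(NA_real_, n, length(res$trace))
      traces[i, ] <- res$trace
    }
  }
  means <- colMeans(Y)
  sds <- apply(Y, 2, stats::sd)
  summary <- data.frame(metric = colnames(Y), mean = means, sd = sds,
                        U = 100 * sds / means, row.names = NULL)
  env <- NULL
  if (!is.null(traces))
    env <- list(times = trace_times, mean = colMeans(traces),
                sd = apply(traces, 2, stats::sd))
  structure(list(X = X, Y = Y, summary = summary, envelope = env,
                 seed = seed, n = n,
                 group_correlation = group_correlation),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> n = %d iterations\n", x$n))
  print(x$summary, digits = 4)
  invisible(x)
}

#' One-at-a-time uncertainty decomposition
#'
#' For each parameter j, all other parameters are held at their means while
#' j is sampled from its distribution; the resulting percent uncertainty
#' U_j = 100 sd(Y) / mean(Y) isolates that parameter's contribution. The
#' relative uncertainty U_j / sigma_Xj (with sigma_Xj in percent of the
#' mean) measures leverage per unit of input uncertainty. Draws for
#' parameter j are identical to a full Monte Carlo run at the same seed.
#'
#' @inheritParams run_mc
#' @return Data frame with one row per (parameter, metric): U_j, sigma_Xj
#'   (percent), and relative U_j / sigma_Xj.
#' @export
one_at_a_time <- function(model, dists, n, seed, group_correlation = list()) {
  out <- NULL
  for (j in seq_along(dists)) {
    dj <- lapply(seq_along(dists), function(i) {
      d <- dists[[i]]
      if (i != j) d$sd <- 0
      d
    })
    mc <- run_mc(model, dj, n, seed, group_correlation)
    sigma_pct <- 100 * dists[[j]]$sd / abs(dists[[j]]$mean)
    rows <- data.frame(parameter = dists[[j]]$name,
                       metric = mc$summary$metric,
                       U_j = mc$summary$U,
                       sigma_X_pct = sigma_pct,
                       relative = if (sigma_pct > 0)
                         mc$summary$U / sigma_pct else NA_real_)
    out <- rbind(out, rows)
  }
  out
}

#' Standardized regression coefficient sensitivity analysis
#'
#' Fits the linear response surface Y = b0 + sum_j b_j X_j by least squares
#' and standardizes each coefficient: SRC_j = b_j sd(X_j) / sd(Y). For an
#' exactly linear model with independent inputs, sum_j SRC_j^2 equals the
#' regression R^2.
#'
#' @param X parameter sample matrix (n x k, named columns).
#' @param Y output metric vector (length n).
#' @return An object of class \code{sensitivity_result}: \code{b0},
#'   \code{b}, \code{src}, \code{sigma_y}, \code{r_squared}.
#' @export
src_analysis <- function(X, Y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k) stop("need more samples than parameters")
  A <- cbind(`(Intercept)` = 1, X)
  qrA <- qr(A)
  if (qrA$rank < ncol(A))
    stop("sample matrix is rank deficient; SRC regression is undefined")
  fit <- stats::lm.fit(A, Y)
  b <- fit$coefficients
  sig_y <- stats::sd(Y)
  src <- b[-1] * apply(X, 2, stats::sd) / sig_y
  rss <- sum(fit$residuals^2)
  tss <- sum((Y - mean(Y))^2)
  structure(list(b0 = unname(b[1]), b = b[-1], src = src, sigma_y = sig_y,
                 r_squared = 1 - rss / tss),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result> R^2 = %.4f\n", x$r_squared))
  print(round(x$src, 4))
  invisible(x)
}
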