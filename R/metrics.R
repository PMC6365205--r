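# common accessors for temperature_field and mrti_series
field_data <- function(x) {
  if (inherits(x, "temperature_field")) return(x$data)
  if (inherits(x, "mrti_series")) return(mrti_average(x))
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  stop("expected a temperature_field, mrti_series, or 4-D array")
}

field_grid <- function(x) {
  if (inherits(x, "temperature_field") || inherits(x, "mrti_series"))
    return(x$grid)
  stop("object carries no grid")
}

#' Spatiotemporal peak temperature rise
#'
#' Global maximum over all voxels and frames. Ties are broken by the
#' earliest frame, then the lowest linear voxel index.
#'
#' @param series a \code{temperature_field}, \code{mrti_series}, or 4-D
#'   array.
#' @return List with \code{value} (deg C), \code{voxel} (i, j, k), and
#'   \code{frame}.
#' @export
peak_metric <- function(series) {
  a <- field_data(series)
  d <- dim(a)
  if (!length(a)) stop("empty series")
  nvox <- prod(d[1:3])
  mx <- max(a)
  hits <- which(a == mx)
  frame <- (hits - 1) %/% nvox + 1
  voxl <- (hits - 1) %% nvox + 1
  pick <- order(frame, voxl)[1]
  list(value = mx,
       voxel = as.integer(arrayInd(voxl[pick], d[1:3])),
       frame = as.integer(frame[pick]))
}

#' Full width at half maximum of a profile through a voxel
#'
#' Extracts the 1-D profile through \code{voxel} along \code{axis} at
#' \code{frame} and measures the width between the two half-maximum
#' crossings, each located by linear interpolation between the bracketing
#' samples.
#'
#' @param series a \code{temperature_field} or \code{mrti_series}.
#' @param voxel (i, j, k) voxel the profile passes through (typically the
#'   peak voxel).
#' @param frame frame index.
#' @param axis 1 = x (long aperture axis), 2 = y (short aperture axis,
#'   "transverse" in the validation sense), 3 = z (longitudinal).
#' @return Width in mm.
#' @export
profile_fwhm <- function(series, voxel, frame, axis) {
  a <- field_data(series)
  grid <- field_grid(series)
  prof <- switch(axis,
                 a[, voxel[2], voxel[3], frame],
                 a[voxel[1], , voxel[3], frame],
                 a[voxel[1], voxel[2], , frame])
  if (max(prof) <= 0) stop("profile peak is not positive")
  w <- fwhm_of_profile(grid_coords(grid, axis), prof)
  if (!is.finite(w))
    stop("FWHM unresolved: profile does not drop below half maximum inside the grid")
  w
}

#' Longitudinal profile center
#'
#' Midpoint of the half-maximum crossings of the longitudinal (z) profile
#' through a voxel; used for the focal-shift comparison.
#'
#' @inheritParams profile_fwhm
#' @return z position in mm (from the transducer apex plane).
#' @export
profile_center_z <- function(series, voxel, frame) {
  a <- field_data(series)
  grid <- field_grid(series)
  prof <- a[voxel[1], voxel[2], , frame]
  z <- grid_coords(grid, 3)
  i0 <- which.max(prof)
  half <- prof[i0] / 2
  left <- right <- NA_real_
  for (i in seq(i0, 2)) if (prof[i - 1] < half && prof[i] >= half) {
    left <- z[i - 1] + (z[i] - z[i - 1]) * (half - prof[i - 1]) /
      (prof[i] - prof[i - 1]); break
  }
  if (i0 < length(prof))
    for (i in seq(i0, length(prof) - 1)) if (prof[i] >= half && prof[i + 1] < half) {
      right <- z[i] + (z[i + 1] - z[i]) * (prof[i] - half) /
        (prof[i] - prof[i + 1]); break
    }
  if (!is.finite(left) || !is.finite(right))
    stop("profile center unresolved inside the grid")
  (left + right) / 2
}

#' Focal comparison metrics of a temperature series
#'
#' Computes the standard validation metric set: spatiotemporal peak
#' temperature rise (and its voxel/frame), transverse FWHM (along the short
#' aperture axis y), longitudinal FWHM (along z), and the longitudinal
#' profile center, all evaluated at the peak frame through the peak voxel.
#'
#' @param series a \code{temperature_field} or \code{mrti_series}.
#' @return An object of class \code{metric_set} (also a named list).
#' @export
compute_metrics <- function(series) {
  pk <- peak_metric(series)
  structure(list(
    peak_C = pk$value, voxel = pk$voxel, frame = pk$frame,
    fwhm_transverse_mm = profile_fwhm(series, pk$voxel, pk$frame, 2),
    fwhm_longitudinal_mm = profile_fwhm(series, pk$voxel, pk$frame, 3),
    center_z_mm = profile_center_z(series, pk$voxel, pk$frame)),
    class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf(paste0("<metric_set> peak %.2f C (frame %d), transverse FWHM ",
                     "%.2f mm, longitudinal FWHM %.2f mm, center z %.2f mm\n"),
              x$peak_C, x$frame, x$fwhm_transverse_mm, x$fwhm_longitudinal_mm,
              x$center_z_mm))
  invisible(x)
}

#' Percent error between simulated and measured metrics
#'
#' E = 100 (Y_sim - Y_exp) / Y_exp per metric, plus the signed absolute
#' differences in native units. Note E is not antisymmetric under exchanging
#' sim and exp (the denominator changes); the signed differences are.
#'
#' @param sim,exp named numeric vectors or \code{metric_set}s sharing names.
#' @return List with \code{percent} and \code{absolute} named vectors.
#' @export
percent_error <- function(sim, exp) {
  nm <- intersect(names(sim), names(exp))
  nm <- nm[vapply(nm, function(n) is.numeric(sim[[n]]) &&
                    length(sim[[n]]) == 1L, logical(1))]
  s <- vapply(nm, function(n) sim[[n]], numeric(1))
  e <- vapply(nm, function(n) exp[[n]], numeric(1))
  if (any(e == 0)) stop("reference metric is zero; percent error undefined")
  list(percent = 100 * (s - e) / e, absolute = s - e)
}

#' Least-squares slope of peak temperature rise versus milk fraction
#'
#' @param milk_percent milk fractions (percent by volume).
#' @param peaks_C peak temperature rises (deg C).
#' @return Slope in deg C per percent milk.
#' @export
slope_vs_composition <- function(milk_percent, peaks_C) {
  stopifnot(length(milk_percent) == length(peaks_C),
            length(milk_percent) >= 2)
  if (length(unique(milk_percent)) < 2)
    stop("milk fractions must not be identical")
  unname(stats::coef(stats::lm(peaks_C ~ milk_percent))[2])
}
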