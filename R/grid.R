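#' Voxel grid
#'
#' A regular, isotropic 3-D voxel lattice shared by all field objects. The z
#' axis is the acoustic propagation (longitudinal) axis measured from the
#' transducer apex plane; x is the long aperture axis and y the short aperture
#' axis of the phased array. Voxel indices are 0-based with voxel centers at
#' \code{origin + (i + 0.5) * spacing} along each axis.
#'
#' @param shape integer vector (nx, ny, nz), all >= 1.
#' @param spacing isotropic voxel edge length in mm, > 0.
#' @param origin length-3 numeric, mm offset of the first grid plane along
#'   (x, y, z). The default centers x and y on the beam axis and puts the
#'   first z plane at 0 (the apex plane).
#' @return An object of class \code{voxel_grid}.
#' @export
voxel_grid <- function(shape, spacing, origin = NULL) {
  shape <- as.integer(round(shape))
  if (length(shape) != 3L || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0)
    stop("'spacing' must be a single positive number (mm)")
  if (is.null(origin))
    origin <- c(-shape[1] * spacing / 2, -shape[2] * spacing / 2, 0)
  if (length(origin) != 3L)
    stop("'origin' must have length 3")
  structure(list(shape = shape, spacing = spacing, origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d @ %g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel-center coordinates along one axis
#'
#' @param grid a \code{voxel_grid}.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return Numeric vector of voxel-center positions in mm.
#' @export
grid_coords <- function(grid, axis) {
  stopifnot(inherits(grid, "voxel_grid"), axis %in% 1:3)
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 0.5) * grid$spacing
}

# shape check used by every field constructor
check_grid_array <- function(grid, arr, what = "array") {
  if (!identical(dim(arr), as.integer(grid$shape)))
    stop(sprintf("%s dimensions (%s) do not match grid shape (%s)", what,
                 paste(dim(arr), collapse = "x"),
                 paste(grid$shape, collapse = "x")))
  invisible(TRUE)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin))
}
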