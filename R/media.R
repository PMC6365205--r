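#' Acoustic and thermal properties of a propagation medium
#'
#' Properties are stored in SI units: attenuation in Np/m at 1 MHz, speed of
#' sound in m/s, density in kg/m^3, thermal conductivity in W/(m C) and
#' volumetric heat capacity in J/(m^3 C). The attenuation frequency dependence
#' is the power law alpha(f) = alpha0 * (f / 1 MHz)^freq_exponent. Note that
#' the speed of sound and the dimensionless frequency exponent are distinct
#' fields even though both are conventionally written c.
#'
#' @param alpha0 pressure attenuation at 1 MHz, Np/m (>= 0).
#' @param sos speed of sound, m/s (> 0).
#' @param rho density, kg/m^3 (> 0).
#' @param kappa thermal conductivity, W/(m C) (>= 0).
#' @param vhc volumetric heat capacity, J/(m^3 C) (> 0).
#' @param freq_exponent power-law exponent of the attenuation-frequency
#'   dependence (dimensionless, default 1: attenuation linear in frequency).
#' @return An object of class \code{medium_properties}.
#' @export
medium_properties <- function(alpha0, sos, rho, kappa, vhc, freq_exponent = 1) {
  stopifnot(alpha0 >= 0, sos > 0, rho > 0, kappa >= 0, vhc > 0)
  structure(list(alpha0 = alpha0, freq_exponent = freq_exponent, sos = sos,
                 rho = rho, kappa = kappa, vhc = vhc),
            class = "medium_properties")
}

#' @export
print.medium_properties <- function(x, ...) {
  cat(sprintf(paste0("<medium_properties> alpha0 %.4g Np/m @1MHz (f^%.2f), ",
                     "c %.1f m/s, rho %.0f kg/m^3, kappa %.3f W/mC, ",
                     "VHC %.4g J/m^3C\n"),
              x$alpha0, x$freq_exponent, x$sos, x$rho, x$kappa, x$vhc))
  invisible(x)
}

#' Pressure attenuation coefficient at a given frequency
#'
#' @param props a \code{medium_properties}.
#' @param freq_hz acoustic frequency in Hz.
#' @return Attenuation in Np/m.
#' @export
attenuation_at <- function(props, freq_hz) {
  props$alpha0 * (freq_hz / 1e6)^props$freq_exponent
}

#' Properties of water used for coupling and reference voxels
#'
#' Acoustically lossless water at room temperature: alpha = 0, c = 1500 m/s,
#' rho = 1000 kg/m^3. Thermal properties (not used where water never heats)
#' take standard room-temperature values.
#'
#' @return A \code{medium_properties} object.
#' @export
water_properties <- function() {
  medium_properties(alpha0 = 0, sos = 1500, rho = 1000,
                    kappa = 0.60, vhc = 4.18e6)
}

# bundled characterization table for the milk-gelatin phantom series
phantom_table <- function() {
  path <- system.file("extdata", "phantom_properties.csv", package = "fusuq",
                      mustWork = TRUE)
  utils::read.csv(path)
}

#' Mean properties of a milk-gelatin phantom composition
#'
#' Returns the measured mean acoustic/thermal properties for one of the four
#' characterized evaporated-milk gelatin phantom compositions (10, 30, 50 or
#' 70 percent milk by volume), converted to SI units.
#'
#' @param milk_fraction percent milk by volume; one of 10, 30, 50, 70.
#' @return A \code{medium_properties} object.
#' @export
phantom_properties <- function(milk_fraction) {
  tab <- phantom_table()
  row <- tab[tab$milk_fraction == milk_fraction, ]
  if (nrow(row) != 1L)
    stop(sprintf("unknown phantom composition %s%%; valid milk fractions: %s",
                 format(milk_fraction),
                 paste(tab$milk_fraction, collapse = ", ")))
  medium_properties(alpha0 = row$alpha0_np_per_cm * 100,   # Np/cm -> Np/m
                    sos    = row$sos_m_s,
                    rho    = row$rho_kg_m3,
                    kappa  = row$kappa_w_mC,
                    vhc    = row$vhc_kj_m3C * 1000)        # kJ -> J
}

#' Relative measurement uncertainties of the phantom properties
#'
#' Fractional standard deviations (e.g. 0.16 = 16 percent) of each measured
#' property for a phantom composition, as used by the Monte Carlo analysis.
#' Acoustic power uncertainty (1.05 percent) is a property of the transducer
#' calibration, not of the phantom, and is returned alongside for convenience.
#'
#' @param milk_fraction percent milk by volume; one of 10, 30, 50, 70.
#' @return Named numeric vector of fractional standard deviations with
#'   elements alpha0, sos, rho, kappa, vhc, power.
#' @export
phantom_uncertainties <- function(milk_fraction) {
  tab <- phantom_table()
  row <- tab[tab$milk_fraction == milk_fraction, ]
  if (nrow(row) != 1L)
    stop(sprintf("unknown phantom composition %s%%; valid milk fractions: %s",
                 format(milk_fraction),
                 paste(tab$milk_fraction, collapse = ", ")))
  c(alpha0 = row$alpha0_rel_sd, sos = row$sos_rel_sd, rho = row$rho_rel_sd,
    kappa = row$kappa_rel_sd, vhc = row$vhc_rel_sd, power = 0.0105)
}

#' Voxelized material model
#'
#' Binds a voxel grid to a per-voxel material label array and a palette
#' mapping label values to \code{medium_properties}.
#'
#' @param grid a \code{voxel_grid}.
#' @param labels integer array of grid shape; every value must index an entry
#'   of \code{palette}.
#' @param palette list of \code{medium_properties}, indexed by label value.
#' @return An object of class \code{material_map}.
#' @export
material_map <- function(grid, labels, palette) {
  check_grid_array(grid, labels, "labels")
  used <- sort(unique(as.integer(labels)))
  if (any(used < 1L) || any(used > length(palette)))
    stop("every label must have a palette entry")
  if (!all(vapply(palette, inherits, logical(1), "medium_properties")))
    stop("palette entries must be medium_properties")
  structure(list(grid = grid, labels = labels, palette = palette),
            class = "material_map")
}

#' @export
print.material_map <- function(x, ...) {
  print(x$grid)
  tab <- table(x$labels)
  cat(sprintf("<material_map> %d material(s); voxel counts: %s\n",
              length(x$palette),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Per-voxel property volume
#'
#' Expands one scalar property of a \code{material_map} palette to a full
#' array over the grid.
#'
#' @param map a \code{material_map}.
#' @param field one of "alpha0", "freq_exponent", "sos", "rho", "kappa", "vhc".
#' @return Numeric array of grid shape.
#' @export
property_volume <- function(map, field) {
  vals <- vapply(map$palette, function(p) p[[field]], numeric(1))
  arr <- vals[as.integer(map$labels)]
  dim(arr) <- map$grid$shape
  arr
}

#' Build the cylindrical phantom-in-water model
#'
#' Extrudes a 2-D circular cross-section along z to form the gelatin phantom
#' cylinder, embedded in water margins. The default margins reproduce the
#' reference simulation extents (161.75 x 85.75 x 70 mm) when used with a
#' 60-mm-diameter, 70-mm-tall phantom at 0.25 mm spacing, giving a
#' 647 x 343 x 280 grid.
#'
#' @param radius_mm cylinder radius (mm); 0 gives an all-water model.
#' @param height_mm cylinder height (mm), extruded along z.
#' @param spacing_mm isotropic voxel spacing (mm).
#' @param phantom \code{medium_properties} of the gelatin.
#' @param margins_mm per-side water margins (x, y, z) in mm added around the
#'   cylinder bounding box.
#' @param origin_z_mm z position (mm from the transducer apex plane) of the
#'   proximal model face; defaults to 80.5 mm so the geometric focus of a
#'   100-mm focal-length source lies 19.5 mm into the phantom.
#' @param water \code{medium_properties} of the surrounding water.
#' @return A \code{material_map} with label 1 = water, 2 = phantom.
#' @export
build_cylinder_model <- function(radius_mm, height_mm, spacing_mm, phantom,
                                 margins_mm = c(50.875, 12.875, 0),
                                 origin_z_mm = 80.5,
                                 water = water_properties()) {
  stopifnot(radius_mm >= 0, height_mm > 0, spacing_mm > 0)
  if (radius_mm > 0 && spacing_mm > radius_mm)
    stop("voxel spacing exceeds the cylinder radius; the mask would be empty")
  if (length(margins_mm) == 1L) margins_mm <- rep(margins_mm, 3)
  ext <- c(2 * radius_mm + 2 * margins_mm[1],
           2 * radius_mm + 2 * margins_mm[2],
           height_mm + 2 * margins_mm[3])
  shape <- as.integer(round(ext / spacing_mm))
  shape <- pmax(shape, 1L)
  grid <- voxel_grid(shape, spacing_mm,
                     origin = c(-shape[1] * spacing_mm / 2,
                                -shape[2] * spacing_mm / 2, origin_z_mm))
  labels <- array(1L, dim = shape)
  if (radius_mm > 0) {
    x <- grid_coords(grid, 1)
    y <- grid_coords(grid, 2)
    z <- grid_coords(grid, 3)
    disk <- outer(x^2, y^2, "+") <= radius_mm^2
    z_in <- z >= origin_z_mm + margins_mm[3] &
            z <= origin_z_mm + margins_mm[3] + height_mm
    lab2d <- array(1L, dim = shape[1:2])
    lab2d[disk] <- 2L
    for (k in which(z_in)) labels[, , k] <- lab2d
  }
  material_map(grid, labels, list(water, phantom))
}

#' Write a property or label volume as NIfTI
#'
#' @param arr numeric or integer array.
#' @param grid the \code{voxel_grid} the array lives on.
#' @param path output file path (".nii" or ".nii.gz").
#' @return The path, invisibly.
#' @export
write_volume <- function(arr, grid, path) {
  check_grid_array(grid, arr)
  img <- RNifti::asNifti(arr, reference = NULL)
  img <- RNifti::`pixdim<-`(img, rep(grid$spacing, 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume written by \code{write_volume}
#'
#' @param path NIfTI file path.
#' @return A plain array with attribute \code{spacing} (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  attr(arr, "spacing") <- RNifti::pixdim(img)[1]
  arr
}

#' Read or write a phantom palette configuration
#'
#' Structured-text (YAML) configuration of phantom compositions in bench
#' units: milk_fraction, alpha0_np_per_cm, sos_m_s, rho_kg_m3, vhc_kj_m3C,
#' kappa_w_mC.
#'
#' @param path config file path.
#' @return For \code{read_phantom_config}, a list of \code{medium_properties}
#'   named by milk fraction.
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- lapply(cfg, function(e)
    medium_properties(alpha0 = e$alpha0_np_per_cm * 100, sos = e$sos_m_s,
                      rho = e$rho_kg_m3, kappa = e$kappa_w_mC,
                      vhc = e$vhc_kj_m3C * 1000))
  names(out) <- vapply(cfg, function(e) as.character(e$milk_fraction),
                       character(1))
  out
}

#' @rdname read_phantom_config
#' @param fractions milk fractions to include (default all four).
#' @export
write_phantom_config <- function(path, fractions = c(10, 30, 50, 70)) {
  cfg <- lapply(fractions, function(fr) {
    p <- phantom_properties(fr)
    list(milk_fraction = fr, alpha0_np_per_cm = p$alpha0 / 100,
         sos_m_s = p$sos, rho_kg_m3 = p$rho, vhc_kj_m3C = p$vhc / 1000,
         kappa_w_mC = p$kappa)
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}
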