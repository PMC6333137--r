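#' Equiangular fan-beam scan geometry
#'
#' Describes a circular full-scan fan-beam acquisition with an equiangular
#' (arc) detector. Defaults follow the simulation study: source-isocenter
#' distance 400 mm, source-detector distance 1100 mm, 720 views over 360
#' degrees. The channel pitch is sized so that the detector arc covers the
#' requested field of view with a small margin.
#'
#' @param sid_mm source-to-isocenter distance, mm.
#' @param sdd_mm source-to-detector distance, mm; must exceed `sid_mm`.
#' @param n_views number of projection views over 360 degrees.
#' @param n_channels number of detector channels.
#' @param fov_radius_mm radius of the scan field of view, mm. Objects must
#'   fit inside this circle.
#' @return an object of class `fan_geometry`.
#' @examples
#' geom <- fan_geometry()
#' geom$pitch_rad * (geom$n_channels - 1) >= 2 * asin(170 / 400)
#' @export
fan_geometry <- function(sid_mm = 400, sdd_mm = 1100, n_views = 720,
                         n_channels = 729, fov_radius_mm = 170) {
  if (!(sdd_mm > sid_mm && sid_mm > 0))
    stop("fan_geometry requires sdd_mm > sid_mm > 0")
  if (n_views < 1) stop("n_views must be >= 1")
  if (n_channels < 2) stop("n_channels must be >= 2")
  if (fov_radius_mm <= 0 || fov_radius_mm >= sid_mm)
    stop("fov_radius_mm must lie in (0, sid_mm)")
  fan <- 2 * asin(fov_radius_mm / sid_mm) * 1.05
  structure(list(sid_mm = sid_mm, sdd_mm = sdd_mm, n_views = n_views,
                 n_channels = n_channels, pitch_rad = fan / (n_channels - 1),
                 fov_radius_mm = fov_radius_mm),
            class = "fan_geometry")
}

#' @export
print.fan_geometry <- function(x, ...) {
  cat(sprintf(
    "fan_geometry: SID %g mm, SDD %g mm, %d views/360deg, %d channels, pitch %.4g mrad, FOV radius %g mm\n",
    x$sid_mm, x$sdd_mm, x$n_views, x$n_channels, 1000 * x$pitch_rad,
    x$fov_radius_mm))
  invisible(x)
}

#' Reconstruction grid specification
#'
#' @param n image side length in pixels (square grid).
#' @param pixel_cm pixel size, cm.
#' @return an object of class `recon_grid`.
#' @export
recon_grid <- function(n = 512, pixel_cm = 0.1) {
  if (n < 2 || pixel_cm <= 0) stop("invalid reconstruction grid")
  structure(list(n = as.integer(n), pixel_cm = pixel_cm), class = "recon_grid")
}

#' Reconstructed CT image
#'
#' The 2-D attenuation image all MAR operations act on. Values are in
#' cm^-1 by default; [to_hu()] converts to Hounsfield units.
#'
#' @param values numeric matrix.
#' @param pixel_cm pixel size, cm (square pixels).
#' @param units `"cm^-1"` or `"HU"`.
#' @param tilt_deg provenance tag: gantry-tilt angle of the scan, degrees.
#' @return an object of class `recon_image`.
#' @export
recon_image <- function(values, pixel_cm, units = "cm^-1", tilt_deg = NA_real_) {
  if (!is.matrix(values) || !all(is.finite(values)))
    stop("recon_image values must be a finite numeric matrix")
  units <- match.arg(units, c("cm^-1", "HU"))
  structure(list(values = values, pixel_cm = pixel_cm, units = units,
                 tilt_deg = tilt_deg),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("recon_image: %d x %d px (%.3g cm/px), units %s, tilt %s deg, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pixel_cm, x$units,
              format(x$tilt_deg), min(x$values), max(x$values)))
  invisible(x)
}

check_same_units <- function(a, b) {
  if (!identical(a$units, b$units))
    stop(sprintf("unit mismatch: %s vs %s (mixing cm^-1 and HU is an error)",
                 a$units, b$units))
  invisible(TRUE)
}
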