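# Fan-beam forward model: ray-driven projection, polychromatic intensity
# formation, noise injection and the log transform.

#' Sinogram container
#' @param values views x channels matrix of log line-integrals (unitless).
#' @param geometry a [fan_geometry()].
#' @return an object of class `sinogram`.
#' @export
sinogram <- function(values, geometry) {
  if (!is.matrix(values) || !all(is.finite(values)))
    stop("sinogram values must be a finite matrix")
  if (nrow(values) != geometry$n_views || ncol(values) != geometry$n_channels)
    stop("sinogram shape does not match geometry")
  structure(list(values = values, geometry = geometry), class = "sinogram")
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("sinogram: %d views x %d channels, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Detected-photon-count sinogram
#' @param counts views x channels matrix of detected counts (>= 0).
#' @param i0 incident photons per channel.
#' @param geometry a [fan_geometry()].
#' @return an object of class `intensity_sinogram`.
#' @export
intensity_sinogram <- function(counts, i0, geometry) {
  if (any(counts < 0)) stop("counts must be >= 0")
  structure(list(counts = counts, i0 = i0, geometry = geometry),
            class = "intensity_sinogram")
}

image_pixel_cm <- function(img) {
  if (inherits(img, "recon_image")) img$pixel_cm
  else if (inherits(img, "material_slice")) img$spacing
  else attr(img, "pixel_cm") %||% stop("pixel size unknown; pass a recon_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_in_fov <- function(values, px, geom) {
  # only pixels carrying signal matter for truncation: background noise and
  # the near-zero attenuation of air are ignored
  nz <- which(abs(values) > 0.01 * max(abs(values)), arr.ind = TRUE)
  if (nrow(nz) == 0) return(invisible(TRUE))
  co <- pixel_coords(nrow(values), ncol(values), px)
  r <- sqrt(co$x[nz[, 2]]^2 + co$y[nz[, 1]]^2)
  if (max(r) > geom$fov_radius_mm / 10 + px)
    stop("image extends beyond the scan field of view")
  invisible(TRUE)
}

#' Fan-beam forward projection
#'
#' Line integrals of an attenuation image along every source-to-channel ray,
#' computed ray-driven with bilinear sampling at a configurable fraction of
#' the pixel size.
#'
#' @param img a [recon_image()] (cm^-1) or a plain matrix with `pixel_cm`.
#' @param geom a [fan_geometry()].
#' @param pixel_cm pixel size when `img` is a bare matrix.
#' @param step_frac sampling step along the ray as a fraction of the pixel
#'   size (default 0.5; smaller is more accurate and slower).
#' @return a [sinogram()] of unitless line integrals.
#' @export
forward_project <- function(img, geom, pixel_cm = NULL, step_frac = 0.5) {
  v <- values_of(img)
  px <- pixel_cm %||% image_pixel_cm(img)
  check_in_fov(v, px, geom)
  out <- .fp_fanbeam_cpp(v, px, geom$sid_mm / 10, geom$n_views,
                         geom$n_channels, geom$pitch_rad, step_frac * px)
  sinogram(out, geom)
}

#' Adjoint of the forward projector
#'
#' Transpose of [forward_project()]'s discretised operator (same ray
#' sampling, transposed accumulation). Used for operator diagnostics, not
#' for image reconstruction -- see [fbp()] for that.
#'
#' @param sino a [sinogram()].
#' @param grid a [recon_grid()].
#' @param step_frac as in [forward_project()].
#' @return a numeric matrix on `grid`.
#' @export
back_project <- function(sino, grid, step_frac = 0.5) {
  .bp_adjoint_cpp(sino$values, grid$n, grid$n, grid$pixel_cm,
                  sino$geometry$sid_mm / 10, sino$geometry$pitch_rad,
                  step_frac * grid$pixel_cm)
}

#' Polychromatic photon-count simulation
#'
#' Forms noise-free detected counts for a material slice under a binned
#' spectrum: `counts = i0 * sum_i w_i * exp(-L_i)` where `L_i` is the
#' monochromatic line integral at bin energy `i`. Each material's indicator
#' image is projected once and the per-energy integrals are assembled from
#' those path lengths, which makes beam hardening and photon starvation
#' emerge from the energy dependence of the attenuation tables.
#'
#' @param slice a `material_slice`.
#' @param sp a [make_spectrum()].
#' @param geom a [fan_geometry()].
#' @param i0 incident photons per channel (default 1e7).
#' @param step_frac ray sampling step fraction, see [forward_project()].
#' @return an [intensity_sinogram()] (noise-free).
#' @export
simulate_polychromatic <- function(slice, sp, geom, i0 = 1e7, step_frac = 0.5) {
  if (i0 <= 0) stop("i0 must be > 0")
  mats <- slice$materials
  mu <- vapply(mats, function(m) attenuation(m, sp$energies),
               numeric(length(sp$energies)))
  mu <- matrix(mu, nrow = length(sp$energies))  # bins x materials
  paths <- vector("list", length(mats))
  for (m in seq_along(mats)) {
    ind <- (slice$labels == m) * 1.0
    if (mats[m] == "air" || !any(ind > 0)) next
    paths[[m]] <- forward_project(ind, geom, pixel_cm = slice$spacing,
                                  step_frac = step_frac)$values
  }
  counts <- 0
  for (b in seq_along(sp$energies)) {
    L <- 0
    for (m in seq_along(mats))
      if (!is.null(paths[[m]])) L <- L + mu[b, m] * paths[[m]]
    counts <- counts + sp$weights[b] * exp(-L)
  }
  if (!is.matrix(counts))  # fully transparent slice: unattenuated beam
    counts <- matrix(counts, geom$n_views, geom$n_channels)
  intensity_sinogram(i0 * counts, i0, geom)
}

#' Poisson counting noise
#'
#' Replaces each detected count by a Poisson draw with that mean.
#'
#' @param isino an [intensity_sinogram()].
#' @param seed RNG seed; the draw is reproducible and the caller's RNG state
#'   is left untouched.
#' @return an [intensity_sinogram()].
#' @export
add_poisson <- function(isino, seed) {
  counts <- isino$counts
  if (any(counts < 0)) stop("counts must be >= 0")
  noisy <- with_seed(seed, rpois(length(counts), lambda = counts))
  intensity_sinogram(matrix(as.numeric(noisy), nrow(counts), ncol(counts)),
                     isino$i0, isino$geometry)
}

#' Log transform of detected counts
#'
#' `values = ln(i0 / counts)`, with zero counts clamped to one photon before
#' the log so that fully starved rays map to the finite ceiling `ln(i0)`.
#'
#' @param isino an [intensity_sinogram()].
#' @return a [sinogram()] of log line-integrals.
#' @export
log_transform <- function(isino) {
  sinogram(log(isino$i0 / pmax(isino$counts, 1)), isino$geometry)
}

#' Gaussian electronic noise on log data
#'
#' @param sino a [sinogram()].
#' @param variance noise variance in the log domain (default 0.001).
#' @param seed RNG seed.
#' @return a [sinogram()].
#' @export
add_gaussian <- function(sino, variance = 0.001, seed) {
  if (variance < 0) stop("variance must be >= 0")
  if (variance == 0) return(sino)
  v <- sino$values
  noise <- with_seed(seed, rnorm(length(v), sd = sqrt(variance)))
  sinogram(v + matrix(noise, nrow(v), ncol(v)), sino$geometry)
}

#' Virtual sinogram of a reconstructed image
#'
#' Monochromatic-model forward projection of a reconstruction, for use when
#' raw projection data are unavailable (the inpainting baselines consume
#' these).
#'
#' @param img a [recon_image()].
#' @param geom a [fan_geometry()].
#' @return a [sinogram()].
#' @export
virtual_sinogram <- function(img, geom) {
  forward_project(img, geom)
}
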