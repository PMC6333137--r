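# Tilted-scan MAR: artifact splitting, modified-SSIM correlation maps,
# per-pixel fusion (T-MAR) and the augmented second pass (AT-MAR).
#
# The method rests on one observation: the difference between co-registered
# ordinary and tilted reconstructions cancels the anatomy and leaves a
# superposition of both scans' metal artifacts. Correlating each scan with
# that map (modified SSIM, luminance factor excluded) scores how much of the
# artifact content each scan carries at each pixel; the fused image takes,
# pixel by pixel, the scan with the lower correlation.

#' Parameters of the modified structural-similarity index
#'
#' The modified SSIM is the product of the contrast and structure factors of
#' the standard SSIM; the luminance factor is excluded because artifact maps
#' and CT images differ grossly in local intensity while sharing structure.
#' Stabilizers default to the standard SSIM constants `c2 = (0.03 R)^2`,
#' `c3 = c2 / 2` (and `c1 = (0.01 R)^2` when the luminance factor is
#' re-enabled for comparison), with `R` the dynamic range of the two input
#' images' union.
#'
#' @param patch odd sliding-window size, pixels (default 5).
#' @param c2,c3,c1 stabilizers; `NULL` derives them from `dynamic_range`.
#' @param alpha,beta,gamma luminance/contrast/structure exponents (default 1).
#' @param dynamic_range value range `R` used for the default stabilizers;
#'   `NULL` measures it from the inputs.
#' @param include_luminance include the luminance factor (full SSIM); only
#'   useful to demonstrate why the modified index is preferred.
#' @return an object of class `ssim_params`.
#' @export
ssim_params <- function(patch = 5, c2 = NULL, c3 = NULL, c1 = NULL,
                        alpha = 1, beta = 1, gamma = 1,
                        dynamic_range = NULL, include_luminance = FALSE) {
  patch <- as.integer(patch)
  if (patch < 3 || patch %% 2 == 0) stop("patch must be odd and >= 3")
  structure(list(patch = patch, c2 = c2, c3 = c3, c1 = c1, alpha = alpha,
                 beta = beta, gamma = gamma, dynamic_range = dynamic_range,
                 include_luminance = include_luminance),
            class = "ssim_params")
}

resolve_ssim_params <- function(p, x, y) {
  if (is.null(p$dynamic_range)) {
    # robust span: a handful of extreme metal pixels must not inflate the
    # stabilizers past the tissue-contrast scale, or the correlation maps
    # saturate at 1 and the selection loses its discrimination
    rng <- quantile(c(x, y), c(0.005, 0.995), names = FALSE)
    p$dynamic_range <- max(rng[2] - rng[1], .Machine$double.eps)
  }
  if (is.null(p$c2)) p$c2 <- (0.03 * p$dynamic_range)^2
  if (is.null(p$c3)) p$c3 <- p$c2 / 2
  if (is.null(p$c1)) p$c1 <- (0.01 * p$dynamic_range)^2
  if (p$c2 <= 0 || p$c3 <= 0) stop("c2 and c3 must be > 0")
  p
}

signed_pow <- function(x, e) if (e == 1) x else sign(x) * abs(x)^e

#' Sliding-window modified SSIM map
#'
#' Per pixel, over its `patch x patch` neighbourhood (uniform window,
#' reflective boundaries):
#' `SSIM'(x, y) = c(x, y)^beta * s(x, y)^gamma`, with contrast factor
#' `c = (2 sx sy + c2) / (sx^2 + sy^2 + c2)` and structure factor
#' `s = (sxy + c3) / (sx sy + c3)`. Values lie in `[-1, 1]` (up to float
#' round-off). With `include_luminance = TRUE` the standard luminance factor
#' `l = (2 mx my + c1) / (mx^2 + my^2 + c1)` multiplies the product.
#'
#' @param x,y matrices or [recon_image()]s of identical shape.
#' @param p an [ssim_params()].
#' @return an object of class `correlation_map` (fields `values`, `patch`).
#' @export
modified_ssim_map <- function(x, y, p = ssim_params()) {
  xv <- values_of(x); yv <- values_of(y)
  stopifnot_same_shape(xv, yv, "SSIM inputs")
  if (p$patch > min(dim(xv))) stop("patch larger than image")
  p <- resolve_ssim_params(p, xv, yv)
  mx <- box_mean(xv, p$patch); my <- box_mean(yv, p$patch)
  vx <- pmax(box_mean(xv * xv, p$patch) - mx * mx, 0)
  vy <- pmax(box_mean(yv * yv, p$patch) - my * my, 0)
  cxy <- box_mean(xv * yv, p$patch) - mx * my
  sx <- sqrt(vx); sy <- sqrt(vy)
  cterm <- (2 * sx * sy + p$c2) / (vx + vy + p$c2)
  sterm <- (cxy + p$c3) / (sx * sy + p$c3)
  val <- signed_pow(cterm, p$beta) * signed_pow(sterm, p$gamma)
  if (isTRUE(p$include_luminance)) {
    lterm <- (2 * mx * my + p$c1) / (mx * mx + my * my + p$c1)
    val <- signed_pow(lterm, p$alpha) * val
  }
  structure(list(values = val, patch = p$patch, params = p),
            class = "correlation_map")
}

#' Artifact superposition map
#'
#' Elementwise difference `ori - tilt` of two co-registered reconstructions.
#' Anatomy cancels; what remains is the superposition of the two scans'
#' metal artifacts.
#'
#' @param ori,tilt [recon_image()]s of identical shape and units.
#' @return an object of class `artifact_map`.
#' @export
artifact_split <- function(ori, tilt) {
  check_same_units(ori, tilt)
  stopifnot_same_shape(ori$values, tilt$values, "images")
  structure(list(values = ori$values - tilt$values,
                 provenance = c(ori$tilt_deg, tilt$tilt_deg)),
            class = "artifact_map")
}

#' Correlation maps of both scans against the artifact map
#'
#' `C_ori = SSIM'(ori_d, art)` and `C_tilt = SSIM'(tilt_d, -art)`; the sign
#' flip keeps the tilted scan's own artifacts positively correlated, because
#' the artifact map is ordinary-minus-tilted. Both maps share one stabilizer
#' pair derived from the union dynamic range of the two images, so their
#' values are directly comparable.
#'
#' @param ori_d,tilt_d denoised reconstructions (matrices or
#'   [recon_image()]s).
#' @param art an [artifact_split()] result consistent with the inputs.
#' @param p an [ssim_params()].
#' @return list with elements `c_ori` and `c_tilt` (correlation maps).
#' @export
correlation_maps <- function(ori_d, tilt_d, art, p = ssim_params()) {
  ov <- values_of(ori_d); tv <- values_of(tilt_d); av <- values_of(art)
  tol <- 1e-8 * max(1, max(abs(ov)), max(abs(tv)))
  if (max(abs(av - (ov - tv))) > tol)
    stop("artifact map is not the difference of the given images")
  p <- resolve_ssim_params(p, ov, tv)
  list(c_ori = modified_ssim_map(ov, av, p),
       c_tilt = modified_ssim_map(tv, -av, p))
}

#' Per-pixel fusion of the two scans
#'
#' The fused image takes the ordinary scan wherever `C_ori < C_tilt` and the
#' tilted scan otherwise (ties go to the tilted scan): a lower correlation
#' with the artifact map marks the less contaminated scan at that pixel.
#'
#' @param ori,tilt [recon_image()]s.
#' @param c_ori,c_tilt correlation maps from [correlation_maps()].
#' @return an object of class `mar_result` with the fused [recon_image()],
#'   the binary source `mask` (TRUE = pixel taken from the ordinary scan)
#'   and both correlation maps.
#' @export
fuse <- function(ori, tilt, c_ori, c_tilt) {
  check_same_units(ori, tilt)
  stopifnot_same_shape(ori$values, tilt$values, "images")
  co <- values_of(c_ori); ct <- values_of(c_tilt)
  stopifnot_same_shape(ori$values, co, "images and correlation maps")
  mask <- co < ct
  fused <- ifelse(mask, ori$values, tilt$values)
  structure(list(
    fused = recon_image(fused, ori$pixel_cm, ori$units),
    mask = mask, c_ori = c_ori, c_tilt = c_tilt),
    class = "mar_result")
}

#' @export
print.mar_result <- function(x, ...) {
  cat(sprintf("mar_result: %d x %d px, %.1f%% of pixels from the ordinary scan\n",
              nrow(x$fused$values), ncol(x$fused$values),
              100 * mean(x$mask)))
  invisible(x)
}

#' T-MAR / AT-MAR pipeline parameters
#'
#' @param sigma Gaussian denoising width, pixels, applied before the
#'   correlation maps (the fused output samples the raw reconstructions
#'   unless `fuse_denoised`). The default is deliberately light: each
#'   scan's own noise is positively correlated with the artifact map, and
#'   this asymmetry steers the selection toward the less noisy scan in
#'   regions without structured artifacts; heavy smoothing erases that cue
#'   and leaves the selection there to chance.
#' @param ssim an [ssim_params()].
#' @param fuse_denoised sample the fused image from the denoised inputs
#'   instead of the raw reconstructions.
#' @param exclude_metal remove segmented metal pixels from the selection
#'   logic and copy them from the ordinary scan (the selection rule is about
#'   artifact regions, not the implants).
#' @param metal_threshold threshold for [segment_metal()]; `NULL` picks
#'   1.2 cm^-1 or 3000 HU by the input units.
#' @param registration_check warn when the bone-mask correlation of the two
#'   inputs falls below 0.5 (inputs are required co-registered; no
#'   registration is performed).
#' @return an object of class `tmar_params`.
#' @export
tmar_params <- function(sigma = 0.5, ssim = ssim_params(),
                        fuse_denoised = FALSE, exclude_metal = TRUE,
                        metal_threshold = NULL, registration_check = TRUE) {
  structure(list(sigma = sigma, ssim = ssim, fuse_denoised = fuse_denoised,
                 exclude_metal = exclude_metal,
                 metal_threshold = metal_threshold,
                 registration_check = registration_check),
            class = "tmar_params")
}

default_metal_threshold <- function(units) {
  if (identical(units, "HU")) 3000 else 1.2
}

check_registration <- function(ori, tilt) {
  thr <- if (identical(ori$units, "HU")) 300 else 0.35
  a <- ori$values > thr; b <- tilt$values > thr
  if (sum(a) < 50 || sum(b) < 50) return(invisible(TRUE))
  r <- suppressWarnings(stats::cor(as.numeric(a), as.numeric(b)))
  if (is.finite(r) && r < 0.5)
    warning(sprintf(
      "bone-mask correlation %.2f < 0.5: inputs may not be co-registered", r))
  invisible(TRUE)
}

#' Tilted-scan metal artifact reduction (T-MAR)
#'
#' Full fusion pipeline: Gaussian denoising of both reconstructions,
#' artifact splitting, modified-SSIM correlation maps, per-pixel fusion.
#' All intermediates are retained in the result for inspection.
#'
#' @param ori ordinary-scan [recon_image()].
#' @param tilt tilted-scan [recon_image()], co-registered with `ori`.
#' @param params a [tmar_params()].
#' @return a `mar_result` with additional fields `ori_d`, `tilt_d` (denoised
#'   inputs), `art` (artifact map), `metal` (metal mask or NULL) and
#'   `params`.
#' @export
tmar_pipeline <- function(ori, tilt, params = tmar_params()) {
  check_same_units(ori, tilt)
  stopifnot_same_shape(ori$values, tilt$values, "images")
  if (isTRUE(params$registration_check)) check_registration(ori, tilt)
  ori_d <- denoise(ori, params$sigma)
  tilt_d <- denoise(tilt, params$sigma)
  art <- artifact_split(ori_d, tilt_d)
  maps <- correlation_maps(ori_d, tilt_d, art, params$ssim)
  res <- if (isTRUE(params$fuse_denoised))
    fuse(ori_d, tilt_d, maps$c_ori, maps$c_tilt)
  else fuse(ori, tilt, maps$c_ori, maps$c_tilt)
  metal <- NULL
  if (isTRUE(params$exclude_metal)) {
    thr <- params$metal_threshold %||% default_metal_threshold(ori$units)
    metal <- segment_metal(ori, thr)
    if (any(metal$values)) {
      res$mask[metal$values] <- TRUE
      res$fused$values[metal$values] <- ori$values[metal$values]
    }
  }
  res$ori_d <- ori_d; res$tilt_d <- tilt_d; res$art <- art
  res$metal <- metal; res$params <- params
  res
}

#' Augmented tilted-scan MAR (AT-MAR)
#'
#' When the tilt cannot supply enough complementary information (both scans
#' keep residual artifacts), a second fusion pass runs the same workflow on
#' the T-MAR intermediate and a sinogram-inpainting MAR image. The
#' augmenting image defaults to NMAR applied to the virtual sinogram of the
#' ordinary scan; any externally produced MAR image can be supplied instead
#' through `augment`.
#'
#' @inheritParams tmar_pipeline
#' @param augment a [recon_image()] to fuse against in the second pass, or
#'   `NULL` to compute an NMAR image from `ori` (requires `geom`).
#' @param geom a [fan_geometry()] used to build the virtual sinogram when
#'   `augment` is NULL.
#' @param stages `2` for the full AT-MAR, `1` to stop after the first pass
#'   (bitwise identical to [tmar_pipeline()]).
#' @return for `stages = 2`, a `mar_result` whose `fused` field is the
#'   stage-2 image, with `stage1` (the T-MAR result) and `augment` retained;
#'   for `stages = 1`, the [tmar_pipeline()] result itself.
#' @export
atmar_pipeline <- function(ori, tilt, params = tmar_params(), augment = NULL,
                           geom = NULL, stages = 2) {
  stage1 <- tmar_pipeline(ori, tilt, params)
  if (stages == 1) return(stage1)
  if (is.null(augment)) {
    if (is.null(geom))
      stop("atmar_pipeline needs `geom` (or a precomputed `augment` image)")
    thr <- params$metal_threshold %||% default_metal_threshold(ori$units)
    metal <- segment_metal(ori, thr)
    vs <- virtual_sinogram(ori, geom)
    trace <- metal_trace(metal, geom, ori$pixel_cm)
    prior <- build_prior(ori, metal)
    grid <- recon_grid(nrow(ori$values), ori$pixel_cm)
    augment <- nmar(vs, trace, prior, grid, metal = metal, uncorrected = ori)
  }
  p2 <- params
  p2$registration_check <- FALSE  # stage-1 output vs inpainting image
  stage2 <- tmar_pipeline(stage1$fused, augment, p2)
  stage2$stage1 <- stage1
  stage2$augment <- augment
  stage2
}
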