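# Sinogram-inpainting comparator methods: metal segmentation and trace
# computation, LI-MAR (per-view linear interpolation across the metal
# trace) and NMAR (the same interpolation in a prior-normalised sinogram).

#' Segment metal from a reconstruction
#'
#' Thresholds the image and closes the result with a 3x3 structuring
#' element so single-pixel holes do not survive.
#'
#' @param img a [recon_image()].
#' @param threshold attenuation threshold, same units as `img`; must sit
#'   above bone values.
#' @param expect_metal warn (not error) if the mask comes out empty.
#' @return an object of class `metal_mask`.
#' @export
segment_metal <- function(img, threshold, expect_metal = FALSE) {
  v <- values_of(img)
  raw <- v > threshold
  if (any(raw)) {
    closed <- EBImage::closing(raw * 1, EBImage::makeBrush(3, "box"))
    raw <- as.matrix(closed) > 0.5
  } else if (isTRUE(expect_metal)) {
    warning("metal expected but no pixel exceeds the threshold")
  }
  structure(list(values = raw, threshold = threshold), class = "metal_mask")
}

#' Metal trace in the sinogram domain
#'
#' Forward-projects the metal mask and marks every sinogram bin whose ray
#' intersects metal.
#'
#' @param mask a [segment_metal()] mask.
#' @param geom a [fan_geometry()].
#' @param pixel_cm pixel size of the mask image, cm.
#' @param dilate_channels widen the trace by this many detector channels on
#'   each side (0 = the bare metal shadow). Segmented masks underestimate
#'   the corrupted penumbra, so inpainting pipelines conventionally discard
#'   a margin around the shadow.
#' @return an object of class `trace_mask` (logical views x channels).
#' @export
metal_trace <- function(mask, geom, pixel_cm, dilate_channels = 0) {
  fp <- forward_project(mask$values * 1, geom, pixel_cm = pixel_cm)
  tr <- fp$values > 1e-9
  if (dilate_channels > 0) {
    k <- matrix(1, 1, 2 * dilate_channels + 1)
    tr <- as.matrix(EBImage::dilate(tr * 1, k)) > 0.5
  }
  structure(list(values = tr), class = "trace_mask")
}

trace_runs <- function(row) {
  r <- rle(row)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Linear inpainting of trace bins
#'
#' Per view, each trace interval is replaced by 1-D linear interpolation
#' between the bordering untouched channels; bins outside the trace are
#' untouched (bitwise).
#'
#' @param sino a [sinogram()].
#' @param trace a [metal_trace()] mask.
#' @return a [sinogram()].
#' @export
inpaint_linear <- function(sino, trace) {
  v <- sino$values
  stopifnot_same_shape(v, trace$values, "sinogram and trace")
  nc <- ncol(v)
  for (vi in seq_len(nrow(v))) {
    tr <- trace$values[vi, ]
    if (!any(tr)) next
    if (all(tr)) stop("metal trace covers an entire view")
    runs <- trace_runs(tr)
    for (k in seq_len(nrow(runs))) {
      s <- runs[k, 1]; e <- runs[k, 2]
      if (s == 1 || e == nc)
        stop("trace interval lacks an untouched neighbour channel")
      left <- v[vi, s - 1]; right <- v[vi, e + 1]
      w <- (seq(s, e) - (s - 1)) / (e + 1 - (s - 1))
      v[vi, s:e] <- left + w * (right - left)
    }
  }
  sinogram(v, sino$geometry)
}

reinsert_metal <- function(img, metal, uncorrected) {
  if (!is.null(metal) && !is.null(uncorrected) && any(metal$values))
    img$values[metal$values] <- uncorrected$values[metal$values]
  img
}

#' LI-MAR: linear-interpolation metal artifact reduction
#'
#' Inpaints the metal trace linearly per view, reconstructs by [fbp()], and
#' re-inserts the metal pixels from the uncorrected reconstruction.
#'
#' @param sino a [sinogram()].
#' @param trace a [metal_trace()] mask.
#' @param grid a [recon_grid()].
#' @param metal optional [segment_metal()] mask for re-insertion.
#' @param uncorrected optional plain-FBP image the metal pixels are copied
#'   from; computed from `sino` when NULL and `metal` is given.
#' @param apodization passed to [fbp()].
#' @return a [recon_image()].
#' @export
limar <- function(sino, trace, grid = recon_grid(), metal = NULL,
                  uncorrected = NULL, apodization = "hann") {
  inp <- inpaint_linear(sino, trace)
  img <- fbp(inp, grid, apodization)
  if (!is.null(metal) && is.null(uncorrected))
    uncorrected <- fbp(sino, grid, apodization)
  reinsert_metal(img, metal, uncorrected)
}

#' Tissue-class prior image for NMAR
#'
#' Flattens the image into classes: air to 0, soft tissue to one
#' representative value (the class median), bone kept as is, metal replaced
#' by the soft-tissue value.
#'
#' @param img a [recon_image()] in cm^-1.
#' @param metal a [segment_metal()] mask.
#' @param cls named thresholds `c(air = ..., bone = ...)` partitioning
#'   air / soft tissue / bone; must be increasing.
#' @return a [recon_image()].
#' @export
build_prior <- function(img, metal, cls = c(air = 0.08, bone = 0.45)) {
  if (!(cls["air"] < cls["bone"]))
    stop("class thresholds must be increasing (air < bone)")
  v <- img$values
  m <- metal$values
  soft <- v >= cls["air"] & v < cls["bone"] & !m
  soft_val <- if (any(soft)) median(v[soft]) else mean(cls)
  out <- v
  out[v < cls["air"] & !m] <- 0
  out[soft] <- soft_val
  out[m] <- soft_val
  recon_image(out, img$pixel_cm, img$units, img$tilt_deg)
}

#' Prior-normalised inpainting of trace bins
#'
#' Divides the sinogram by the forward projection of the prior, interpolates
#' the trace linearly in that normalised domain, and multiplies back. Bins
#' outside the trace are untouched (bitwise).
#'
#' @param sino a [sinogram()].
#' @param trace a [metal_trace()] mask.
#' @param prior_sino [sinogram()] of the prior image (same geometry).
#' @return a [sinogram()].
#' @export
inpaint_normalized <- function(sino, trace, prior_sino) {
  ps <- prior_sino$values
  if (max(ps) <= 0) stop("prior projection is not positive")
  ps <- pmax(ps, 1e-6 * max(ps))
  norm <- sinogram(sino$values / ps, sino$geometry)
  inp <- inpaint_linear(norm, trace)
  out <- sino$values
  out[trace$values] <- inp$values[trace$values] * ps[trace$values]
  sinogram(out, sino$geometry)
}

#' NMAR: normalised metal artifact reduction
#'
#' @inheritParams limar
#' @param prior a [build_prior()] image.
#' @return a [recon_image()].
#' @export
nmar <- function(sino, trace, prior, grid = recon_grid(), metal = NULL,
                 uncorrected = NULL, apodization = "hann") {
  prior_sino <- virtual_sinogram(prior, sino$geometry)
  inp <- inpaint_normalized(sino, trace, prior_sino)
  img <- fbp(inp, grid, apodization)
  if (!is.null(metal) && is.null(uncorrected))
    uncorrected <- fbp(sino, grid, apodization)
  reinsert_metal(img, metal, uncorrected)
}
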