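# ROI-based quantitative evaluation: mean absolute percentage error against
# an artifact-free reference, and the multi-method comparison report.

#' Region-of-interest set
#'
#' @param masks named list of logical matrices; each must be nonempty and
#'   should exclude metal pixels.
#' @param tissue_class optional character vector of tissue labels per ROI.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(masks, tissue_class = NULL) {
  if (length(masks) == 0) stop("roi_set needs at least one mask")
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    names(masks) <- paste0("roi", seq_along(masks))
  for (m in masks) if (!any(m)) stop("empty ROI mask")
  structure(list(masks = masks, tissue_class = tissue_class),
            class = "roi_set")
}

roi_union <- function(roi) Reduce(`|`, roi$masks)

#' Default soft-tissue ROI from phantom ground truth
#'
#' The soft-tissue label mask of the ground-truth slice, eroded by 2 pixels
#' to stay clear of class boundaries, with a 3-pixel dilation of the metal
#' mask removed so implant blooming never enters the statistics.
#'
#' @param slice the ground-truth `material_slice` the scan was simulated
#'   from.
#' @param metal optional [segment_metal()] mask (defaults to the slice's own
#'   metal labels).
#' @return a [roi_set()] with one `soft_tissue` mask.
#' @export
default_roi <- function(slice, metal = NULL) {
  soft <- Reduce(`|`, lapply(intersect(SOFT_TISSUE_MATERIALS,
                                       slice$materials),
                             slice_mask, slice = slice))
  soft <- as.matrix(EBImage::erode(soft * 1, EBImage::makeBrush(5, "box"))) > 0.5
  mmask <- if (is.null(metal)) {
    mats <- metal_materials(slice)
    if (length(mats)) Reduce(`|`, lapply(mats, slice_mask, slice = slice))
    else matrix(FALSE, nrow(slice$labels), ncol(slice$labels))
  } else metal$values
  if (any(mmask)) {
    grown <- as.matrix(EBImage::dilate(mmask * 1,
                                       EBImage::makeBrush(7, "box"))) > 0.5
    soft <- soft & !grown
  }
  roi_set(list(soft_tissue = soft), tissue_class = "soft_tissue")
}

#' Artifact-corridor ROIs between two implants
#'
#' Circular ROIs placed along the segment joining the two metal
#' cross-section centroids -- the region the inter-implant artifacts
#' traverse -- intersected with the eroded soft-tissue mask of
#' [default_roi()]. This mirrors the common evaluation practice of marking
#' ROIs in the artifact-affected soft tissue; it falls back to the full
#' soft-tissue mask when fewer than two metal components are present or the
#' corridor holds no soft tissue.
#'
#' @param slice ground-truth `material_slice` of the ordinary scan.
#' @param n_disks number of disks along the corridor.
#' @param frac_radius disk radius as a fraction of the implant separation.
#' @return a [roi_set()].
#' @export
roi_between_metals <- function(slice, n_disks = 5, frac_radius = 0.15) {
  base <- default_roi(slice)
  soft <- base$masks[[1]]
  mats <- metal_materials(slice)
  mmask <- if (length(mats)) Reduce(`|`, lapply(mats, slice_mask,
                                                slice = slice))
  else matrix(FALSE, nrow(slice$labels), ncol(slice$labels))
  cc <- EBImage::bwlabel(mmask)
  if (max(cc) < 2) return(base)
  n <- nrow(slice$labels); px <- slice$spacing
  co <- pixel_coords(n, n, px)
  cents <- lapply(seq_len(max(cc)), function(k) {
    idx <- which(cc == k, arr.ind = TRUE)
    c(x = mean(co$x[idx[, 2]]), y = mean(co$y[idx[, 1]]))
  })
  # the two largest components
  sizes <- tabulate(cc[cc > 0])
  ord <- order(sizes, decreasing = TRUE)[1:2]
  c1 <- cents[[ord[1]]]; c2 <- cents[[ord[2]]]
  sep <- sqrt(sum((c1 - c2)^2))
  ts <- seq(0.2, 0.8, length.out = n_disks)
  corridor <- Reduce(`|`, lapply(ts, function(t) {
    p <- c1 + t * (c2 - c1)
    disk_mask(n, px, p[1], p[2], frac_radius * sep)
  }))
  m <- corridor & soft
  if (sum(m) < 20) return(base)
  roi_set(list(corridor = m), tissue_class = "soft_tissue")
}

#' Mean absolute percentage error over an ROI
#'
#' `100 * mean(|img - ref| / |ref|)` over the union of the ROI masks.
#'
#' @param img,ref [recon_image()]s of identical shape and units.
#' @param roi a [roi_set()].
#' @return MAPE in percent.
#' @export
mape <- function(img, ref, roi) {
  check_same_units(img, ref)
  stopifnot_same_shape(img$values, ref$values, "images")
  m <- roi_union(roi)
  r <- ref$values[m]
  if (any(r == 0)) stop("reference is zero inside the ROI; MAPE undefined")
  100 * mean(abs(img$values[m] - r) / abs(r))
}

#' Compare MAR methods against a reference
#'
#' @param methods named list of [recon_image()]s.
#' @param ref the artifact-free reference [recon_image()].
#' @param roi a [roi_set()].
#' @return a data.frame of class `eval_report` with columns `method` and
#'   `mape_pct`, sorted by increasing error.
#' @export
compare_methods <- function(methods, ref, roi) {
  if (is.null(names(methods))) stop("methods must be a named list")
  err <- vapply(methods, mape, numeric(1), ref = ref, roi = roi)
  out <- data.frame(method = names(methods), mape_pct = unname(err),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mape_pct, out$method), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("eval_report", "data.frame")
  out
}

#' Write an evaluation report as CSV
#' @param report a [compare_methods()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
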