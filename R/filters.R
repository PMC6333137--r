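# Image-domain filters used by the fusion method.

gaussian_kernel <- function(sigma) {
  r <- as.integer(ceiling(4 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian denoising
#'
#' Separable Gaussian smoothing with reflective boundaries. The kernel is
#' the normalised discrete Gaussian truncated at +/- ceiling(4 sigma)
#' pixels; `sigma = 0` returns the input unchanged.
#'
#' @param img a [recon_image()] or numeric matrix.
#' @param sigma kernel standard deviation, pixels (>= 0).
#' @return same type as `img`.
#' @export
denoise <- function(img, sigma = 1) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(img)
  v <- values_of(img)
  out <- .sep_filter_cpp(v, gaussian_kernel(sigma))
  if (inherits(img, "recon_image")) {
    img$values <- out
    img
  } else out
}

# patch-mean filter (uniform window), reflective boundary
box_mean <- function(m, patch) {
  .sep_filter_cpp(m, rep(1 / patch, patch))
}
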