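# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a master seed
#'
#' Expands one user-facing seed into independent per-stage seeds (Poisson
#' noise, Gaussian noise, ...) so that toggling one noise source does not
#' change the draws of another. Uses a Lehmer step modulo the Mersenne prime
#' 2^31 - 1, so results stay within R's integer range.
#'
#' @param seed master seed (integer).
#' @param stage stage index (integer >= 0).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  s <- (abs(as.numeric(seed)) %% 2147483647) + 1
  for (k in seq_len(stage + 1L)) s <- (s * 48271) %% 2147483647
  as.integer(s)
}

# fractional pixel-center coordinate grids for an nr x nc image (cm)
pixel_coords <- function(nr, nc, px) {
  list(x = (seq_len(nc) - (nc + 1) / 2) * px,
       y = ((nr + 1) / 2 - seq_len(nr)) * px)
}

#' Binary disk mask on the package image grid
#'
#' Convenience for building test objects and ROIs: pixels whose centre lies
#' within `radius` of `(cx, cy)` (cm, isocenter origin).
#'
#' @param n image side, pixels. @param px pixel size, cm.
#' @param cx,cy disk centre, cm. @param radius disk radius, cm.
#' @return logical n x n matrix.
#' @export
disk_mask <- function(n, px, cx = 0, cy = 0, radius = 1) {
  co <- pixel_coords(n, n, px)
  outer(co$y, co$x, function(y, x) (x - cx)^2 + (y - cy)^2 <= radius^2)
}

stopifnot_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("%s must have identical dimensions", what))
  invisible(TRUE)
}

values_of <- function(x) {
  if (is.matrix(x)) x else if (is.list(x) && !is.null(x$values)) x$values
  else stop("expected a matrix or an object with a $values matrix")
}

# materials that are not implants; everything else counts as metal
NON_METAL_MATERIALS <- c("air", "water", "soft_tissue", "adipose", "bone",
                         "gypsum")

metal_materials <- function(slice_or_phantom) {
  setdiff(slice_or_phantom$materials, NON_METAL_MATERIALS)
}

# anatomical soft-tissue classes used for evaluation ROIs
SOFT_TISSUE_MATERIALS <- c("soft_tissue", "adipose")
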