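# Beam physics: x-ray spectrum binning and material attenuation lookups.
# Tables are shipped with the package (inst/extdata) so simulations are
# deterministic and need no network access.

the <- new.env(parent = emptyenv())

att_table <- function(path = NULL) {
  key <- if (is.null(path)) ".att" else path
  if (is.null(the[[key]])) {
    f <- if (is.null(path))
      system.file("extdata", "attenuation.csv", package = "tiltmar")
    else path
    the[[key]] <- read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
  }
  the[[key]]
}

spectrum_table <- function(path = NULL) {
  key <- if (is.null(path)) ".sp" else path
  if (is.null(the[[key]])) {
    f <- if (is.null(path))
      system.file("extdata", "spectrum_w120.csv", package = "tiltmar")
    else path
    the[[key]] <- read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
  }
  the[[key]]
}

#' Materials known to the attenuation table
#' @return character vector of material names.
#' @export
materials <- function() unique(att_table()$material)

#' Linear attenuation coefficient of a material
#'
#' Looks up the bundled mass-attenuation table and interpolates log-log
#' between tabulated energies; the result is scaled by the material's bulk
#' density to a linear coefficient in cm^-1.
#'
#' @param material one of [materials()].
#' @param energy_kev photon energy (or vector of energies), keV; must lie
#'   within the tabulated range.
#' @return linear attenuation, cm^-1 (vectorised over `energy_kev`).
#' @examples
#' attenuation("water", 60)   # ~0.206 cm^-1
#' @export
attenuation <- function(material, energy_kev) {
  tab <- att_table()
  rows <- tab[tab$material == material, ]
  if (nrow(rows) == 0)
    stop(sprintf("unknown material '%s' (known: %s)", material,
                 paste(materials(), collapse = ", ")))
  if (any(energy_kev < min(rows$energy_kev) | energy_kev > max(rows$energy_kev)))
    stop(sprintf("energy outside tabulated range [%g, %g] keV for %s",
                 min(rows$energy_kev), max(rows$energy_kev), material))
  mr <- exp(stats::approx(log(rows$energy_kev), log(rows$mu_rho_cm2_g),
                          log(energy_kev))$y)
  mr * rows$density_g_cm3[1]
}

#' Binned polychromatic x-ray spectrum
#'
#' Collapses a tabulated 120 kVp tungsten-anode spectral shape onto `n_bins`
#' equally spaced monochromatic bins spanning up to the tube voltage. For the
#' default (120, 6) this yields bins at 20, 40, 60, 80, 100 and 120 keV, each
#' weighted by the fluence integrated over +/- 10 keV around the bin centre.
#'
#' @param kvp tube voltage, kV; in `[40, 150]`.
#' @param n_bins number of energy bins (>= 1). With `n_bins = 1` the single
#'   bin sits at the spectrum's mean energy with weight 1.
#' @return an object of class `spectrum` with fields `energies` (keV) and
#'   `weights` (sum to 1).
#' @export
make_spectrum <- function(kvp = 120, n_bins = 6) {
  if (kvp < 40 || kvp > 150) stop("kvp must be in [40, 150]")
  if (n_bins < 1) stop("n_bins must be >= 1")
  tab <- spectrum_table()
  tab <- tab[tab$energy_kev <= kvp, ]
  if (n_bins > nrow(tab))
    stop("n_bins exceeds the number of distinct tabulated energies")
  if (n_bins == 1) {
    w <- tab$fluence / sum(tab$fluence)
    return(structure(list(energies = sum(tab$energy_kev * w), weights = 1),
                     class = "spectrum"))
  }
  half <- kvp / n_bins / 2
  centres <- (seq_len(n_bins)) * kvp / n_bins
  w <- vapply(centres, function(e0)
    sum(tab$fluence[tab$energy_kev > e0 - half & tab$energy_kev <= e0 + half]),
    numeric(1))
  if (sum(w) <= 0) stop("spectrum table has no fluence below kvp")
  structure(list(energies = centres, weights = w / sum(w)), class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("spectrum:", paste(sprintf("%g keV (%.3f)", x$energies, x$weights),
                         collapse = ", "), "\n")
  invisible(x)
}

#' Fluence-weighted effective attenuation over a spectrum
#'
#' @param material one of [materials()].
#' @param sp a [make_spectrum()] object.
#' @return effective linear attenuation, cm^-1.
#' @export
effective_mu <- function(material, sp) {
  sum(sp$weights * attenuation(material, sp$energies))
}
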