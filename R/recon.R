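# Equiangular fan-beam filtered backprojection (Kak-Slaney form): cosine
# weighting, ramp filtering along the channel direction, distance-weighted
# backprojection.

fan_ramp_kernel <- function(n_chan, pitch) {
  # impulse response of the equiangular-modified ramp, sampled at the
  # channel pitch: g(k) = 0.5 * (gk / sin gk)^2 * h(k), with h the standard
  # band-limited ramp kernel.
  k <- -(n_chan - 1):(n_chan - 1)
  h <- numeric(length(k))
  h[k == 0] <- 1 / (4 * pitch^2)
  odd <- k %% 2 != 0
  h[odd] <- -1 / (pi * k[odd] * pitch)^2
  gk <- k * pitch
  corr <- ifelse(k == 0, 1, (gk / sin(gk))^2)
  0.5 * corr * h
}

filter_projections <- function(p1, pitch, apodization = c("hann", "ramp")) {
  apodization <- match.arg(apodization)
  n_chan <- ncol(p1)
  g <- fan_ramp_kernel(n_chan, pitch)
  N <- 2^ceiling(log2(length(g) + n_chan))
  gpad <- numeric(N)
  gpad[1:(2 * n_chan - 1)] <- g           # linear convolution via padding
  G <- fft(gpad)
  if (apodization == "hann") {
    f <- pmin(0:(N - 1), N - (0:(N - 1))) / N   # cycles/sample, 0..0.5
    G <- G * (0.5 * (1 + cos(2 * pi * f)))
  }
  P <- matrix(0, N, nrow(p1))
  P[1:n_chan, ] <- t(p1)
  Q <- Re(mvfft(mvfft(P) * G, inverse = TRUE)) / N
  # row m of the linear convolution aligned so output channel c sits at
  # index c + (n_chan - 1)
  t(Q[n_chan:(2 * n_chan - 1), , drop = FALSE]) * pitch
}

#' Fan-beam filtered backprojection
#'
#' Reconstructs an attenuation image from a full-scan equiangular fan-beam
#' sinogram: cosine pre-weighting by the source-to-isocenter distance,
#' Hann-apodized ramp filtering (pure ramp available), and
#' inverse-square-distance-weighted backprojection.
#'
#' @param sino a [sinogram()] covering 360 degrees.
#' @param grid a [recon_grid()].
#' @param apodization `"hann"` (default) or `"ramp"`.
#' @param tilt_deg provenance tag copied to the output image.
#' @return a [recon_image()] in cm^-1.
#' @export
fbp <- function(sino, grid = recon_grid(), apodization = c("hann", "ramp"),
                tilt_deg = NA_real_) {
  apodization <- match.arg(apodization)
  geom <- sino$geometry
  D <- geom$sid_mm / 10
  gamma <- (seq_len(geom$n_channels) - (geom$n_channels + 1) / 2) *
    geom$pitch_rad
  p1 <- sweep(sino$values, 2, D * cos(gamma), `*`)
  q <- filter_projections(p1, geom$pitch_rad, apodization)
  img <- .fbp_backproject_cpp(q, D, geom$pitch_rad, grid$n, grid$n,
                              grid$pixel_cm)
  # pixels outside the scan FOV see only partial view coverage; zero them
  img[!disk_mask(grid$n, grid$pixel_cm, radius = geom$fov_radius_mm / 10)] <- 0
  recon_image(img, grid$pixel_cm, units = "cm^-1", tilt_deg = tilt_deg)
}

#' Convert an attenuation image to Hounsfield units
#'
#' `HU = 1000 * (mu - mu_water) / mu_water`.
#'
#' @param img a [recon_image()] in cm^-1.
#' @param mu_water water attenuation at the effective beam energy, cm^-1.
#' @return a [recon_image()] in HU.
#' @export
to_hu <- function(img, mu_water) {
  if (!identical(img$units, "cm^-1")) stop("to_hu expects a cm^-1 image")
  if (mu_water <= 0) stop("mu_water must be > 0")
  recon_image(1000 * (img$values - mu_water) / mu_water, img$pixel_cm,
              units = "HU", tilt_deg = img$tilt_deg)
}
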