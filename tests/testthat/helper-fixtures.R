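# Shared fixtures: small geometries, analytic phantoms, and independent
# oracles (dense-sampling projector, scalar per-patch SSIM).

tiny_geom <- function(n_views = 16, n_channels = 25, fov = 60)
  fan_geometry(400, 1100, n_views, n_channels, fov)

# dense-sampling line-integral oracle over the same ray set as the
# package projector (independent integration, 0.1-pixel steps)
oracle_forward_project <- function(img, px, geom, step_frac = 0.1) {
  nr <- nrow(img); nc <- ncol(img)
  sid <- geom$sid_mm / 10
  pitch <- geom$pitch_rad
  gamma0 <- -0.5 * (geom$n_channels - 1) * pitch
  rimg <- 0.5 * px * sqrt(nr^2 + nc^2) + px
  out <- matrix(0, geom$n_views, geom$n_channels)
  bilin <- function(r, c) {
    r0 <- floor(r); c0 <- floor(c); fr <- r - r0; fc <- c - c0
    v <- 0
    for (dr in 0:1) for (dc in 0:1) {
      ri <- r0 + dr; ci <- c0 + dc
      if (ri >= 0 && ri < nr && ci >= 0 && ci < nc)
        v <- v + (if (dr) fr else 1 - fr) * (if (dc) fc else 1 - fc) *
          img[ri + 1, ci + 1]
    }
    v
  }
  for (v in seq_len(geom$n_views)) {
    beta <- 2 * pi * (v - 1) / geom$n_views
    s <- c(-sid * sin(beta), sid * cos(beta))
    d0 <- c(sin(beta), -cos(beta))
    for (m in seq_len(geom$n_channels)) {
      g <- gamma0 + (m - 1) * pitch
      d <- c(d0[1] * cos(g) - d0[2] * sin(g), d0[1] * sin(g) + d0[2] * cos(g))
      sd <- sum(s * d)
      disc <- sd^2 - (sid^2 - rimg^2)
      if (disc <= 0) next
      t0 <- -sd - sqrt(disc); t1 <- -sd + sqrt(disc)
      nstep <- ceiling((t1 - t0) / (step_frac * px))
      h <- (t1 - t0) / nstep
      tt <- t0 + (seq_len(nstep) - 0.5) * h
      acc <- 0
      for (t in tt) {
        p <- s + t * d
        acc <- acc + bilin(0.5 * (nr - 1) - p[2] / px, p[1] / px + 0.5 * (nc - 1))
      }
      out[v, m] <- acc * h
    }
  }
  out
}

# scalar modified-SSIM of two patches, straight from the factor definitions
oracle_ssim_patch <- function(px, py, c2, c3, luminance = FALSE, c1 = 0) {
  n <- length(px)
  mx <- mean(px); my <- mean(py)
  vx <- mean(px^2) - mx^2; vy <- mean(py^2) - my^2
  vx <- max(vx, 0); vy <- max(vy, 0)
  cxy <- mean(px * py) - mx * my
  sx <- sqrt(vx); sy <- sqrt(vy)
  val <- (2 * sx * sy + c2) / (vx + vy + c2) * (cxy + c3) / (sx * sy + c3)
  if (luminance) val <- val * (2 * mx * my + c1) / (mx^2 + my^2 + c1)
  val
}

# reflective (half-sample) patch extraction matching the package filters
oracle_patch <- function(m, i, j, patch) {
  r <- (patch - 1) / 2
  refl <- function(k, n) {
    k <- k - 1
    while (k < 0 || k >= n) {
      if (k < 0) k <- -k - 1
      if (k >= n) k <- 2 * n - k - 1
    }
    k + 1
  }
  idx_i <- vapply((i - r):(i + r), refl, numeric(1), n = nrow(m))
  idx_j <- vapply((j - r):(j + r), refl, numeric(1), n = ncol(m))
  m[idx_i, idx_j]
}

# deterministic two-scan streak fixture: shared anatomy, complementary
# bright/dark streak sets (dark bands emulate the inter-implant artifact)
streak_fixture <- function(n = 128, px = 0.1) {
  co <- tiltmar:::pixel_coords(n, n, px)
  base <- 0.20 +
    0.02 * outer(co$y, co$x, function(y, x) exp(-(x^2 + y^2) / 8)) +
    0.05 * disk_mask(n, px, 2, 1.5, 1.2) +
    0.04 * disk_mask(n, px, -2.5, -1, 1.5)
  streak <- function(angle_deg, offset, width, amp) {
    th <- angle_deg * pi / 180
    d <- outer(co$y, co$x, function(y, x) x * cos(th) + y * sin(th) - offset)
    amp * exp(-(d / width)^2)
  }
  ori <- base + streak(15, 0.5, 0.35, -0.12) + streak(15, -1.5, 0.3, 0.08) +
    streak(20, 2.5, 0.3, -0.09)
  tlt <- base + streak(80, 0.3, 0.35, -0.10) + streak(75, -2, 0.3, 0.06)
  list(ori = recon_image(ori, px, tilt_deg = 0),
       tilt = recon_image(tlt, px, tilt_deg = 10),
       ref = recon_image(base, px),
       roi = roi_set(list(all = matrix(TRUE, n, n))))
}

# small water-disk sinogram used by the inpainting tests
disk_sinogram <- function(n = 96, px = 0.2, radius = 6, mu = 0.2,
                          geom = fan_geometry(400, 1100, 72, 181, 120)) {
  img <- disk_mask(n, px, radius = radius) * mu
  forward_project(img, geom, pixel_cm = px)
}
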