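test_that("projector basics: empty object, disk chord length", {
  geom <- tiny_geom(n_views = 8, n_channels = 41, fov = 100)
  zero <- forward_project(matrix(0, 64, 64), geom, pixel_cm = 0.25)
  expect_true(all(zero$values == 0))

  px <- 0.1
  img <- disk_mask(128, px, radius = 5) * 0.2
  geom2 <- fan_geometry(400, 1100, 4, 41, 80)
  sino <- forward_project(img, geom2, pixel_cm = px)
  central <- sino$values[1, 21]
  expect_lt(abs(central - 2 * 5 * 0.2) / 2, 0.01)
})

test_that("projector matches a dense-sampling oracle on a random image", {
  set.seed(42)
  img <- matrix(runif(32 * 32), 32, 32)
  px <- 0.3
  geom <- tiny_geom(n_views = 6, n_channels = 21, fov = 75)
  got <- forward_project(img, geom, pixel_cm = px, step_frac = 0.5)$values
  want <- oracle_forward_project(img, px, geom, step_frac = 0.1)
  scale <- max(abs(want))
  expect_lt(max(abs(got - want)) / scale, 0.005)
})

test_that("back projector is the adjoint of the forward projector", {
  set.seed(7)
  geom <- tiny_geom(n_views = 32, n_channels = 41, fov = 50)
  grid <- recon_grid(32, 0.2)
  x <- matrix(runif(32 * 32), 32, 32)
  Px <- forward_project(x, geom, pixel_cm = 0.2)$values
  y <- matrix(runif(length(Px)), nrow(Px), ncol(Px))
  Pty <- back_project(sinogram(y, geom), grid)
  lhs <- sum(Px * y); rhs <- sum(x * Pty)
  expect_lt(abs(lhs - rhs) / abs(lhs), 0.01)
})

test_that("image reaching past the field of view is refused", {
  geom <- fan_geometry(400, 1100, 8, 41, fov_radius_mm = 50)
  img <- disk_mask(64, 0.25, radius = 7) * 0.2  # 7 cm object, 5 cm FOV
  expect_error(forward_project(img, geom, pixel_cm = 0.25), "field of view")
})

test_that("polychromatic counts: air slice, monochromatic limit, hardening", {
  geom <- tiny_geom(n_views = 8, n_channels = 31, fov = 100)
  sp <- make_spectrum(120, 6)
  n <- 48; px <- 0.4
  air <- structure(list(labels = matrix(1L, n, n),
                        materials = c("air", "water"), spacing = px,
                        tilt_deg = 0), class = "material_slice")
  isino <- simulate_polychromatic(air, sp, geom, i0 = 1e7)
  expect_equal(isino$counts, matrix(1e7, geom$n_views, geom$n_channels),
               tolerance = 1e-6)

  water <- air
  water$labels[disk_mask(n, px, radius = 6)] <- 2L
  sp1 <- make_spectrum(120, 1)
  mono <- simulate_polychromatic(water, sp1, geom, i0 = 1e7)
  L <- forward_project((water$labels == 2L) * attenuation("water", sp1$energies),
                       geom, pixel_cm = px)
  expect_equal(mono$counts, 1e7 * exp(-L$values), tolerance = 1e-10)

  # beam hardening: effective mu falls with chord length
  poly <- simulate_polychromatic(water, sp, geom, i0 = 1e7)
  chord <- forward_project((water$labels == 2L) * 1, geom, pixel_cm = px)$values
  mid <- which(chord[1, ] > 11)
  edge <- which(chord[1, ] > 2 & chord[1, ] < 5)
  eff <- -log(poly$counts[1, ] / 1e7) / chord[1, ]
  expect_lt(mean(eff[mid]), mean(eff[edge]))
})

test_that("Poisson noise: determinism, zero mean preservation, concentration", {
  geom <- tiny_geom(n_views = 4, n_channels = 11)
  counts <- matrix(1e7, 4, 11)
  counts[1, 1] <- 0
  isino <- intensity_sinogram(counts, 1e7, geom)
  a <- add_poisson(isino, seed = 11)
  b <- add_poisson(isino, seed = 11)
  expect_identical(a$counts, b$counts)
  expect_identical(a$counts[1, 1], 0)
  dev <- abs(a$counts[-1] - 1e7) / sqrt(1e7)
  expect_true(all(dev < 5))
})

test_that("log transform clamps photon starvation to one count", {
  geom <- tiny_geom(n_views = 2, n_channels = 3)
  counts <- matrix(c(1e7, 0, 12, 1e5, 5e6, 1), 2, 3)
  sino <- log_transform(intensity_sinogram(counts, 1e7, geom))
  expect_equal(sino$values[1, 1], 0)
  expect_equal(sino$values[2, 1], log(1e7))
  ord <- order(counts)
  expect_true(all(diff(sino$values[ord]) <= 0))
})

test_that("Gaussian log-domain noise has the requested variance", {
  geom <- fan_geometry(400, 1100, 720, 365, 170)
  sino <- sinogram(matrix(1, 720, 365), geom)
  expect_identical(add_gaussian(sino, 0, seed = 1)$values, sino$values)
  noisy <- add_gaussian(sino, 0.001, seed = 5)
  expect_identical(noisy$values, add_gaussian(sino, 0.001, seed = 5)$values)
  v <- var(as.numeric(noisy$values - sino$values))
  expect_lt(abs(v - 0.001) / 0.001, 0.05)
  expect_error(add_gaussian(sino, -1, seed = 1), "variance")
})

test_that("noise injection leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  geom <- tiny_geom(n_views = 2, n_channels = 3)
  invisible(add_poisson(intensity_sinogram(matrix(10, 2, 3), 10, geom), 4))
  invisible(add_gaussian(sinogram(matrix(0, 2, 3), geom), 0.001, 4))
  expect_identical(.Random.seed, before)
})

test_that("virtual sinogram is linear and vanishes for a zero image", {
  geom <- tiny_geom(n_views = 8, n_channels = 31, fov = 100)
  img <- recon_image(disk_mask(48, 0.4, radius = 6) * 0.2, 0.4)
  v1 <- virtual_sinogram(img, geom)$values
  img3 <- recon_image(img$values * 3, 0.4)
  expect_equal(virtual_sinogram(img3, geom)$values, 3 * v1,
               tolerance = 1e-12)
  expect_true(all(virtual_sinogram(recon_image(matrix(0, 48, 48), 0.4),
                                   geom)$values == 0))
})
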