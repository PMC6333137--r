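test_that("pelvis phantom has two rods whose cross-section area matches the cylinder", {
  cfg <- pelvis_config(n_xy = 512, spacing = 0.1, z_half = 0.3)
  ph <- make_pelvis_phantom(cfg)
  sl <- oblique_slice(ph, 0)
  metal <- slice_mask(sl, cfg$metal)
  cc <- EBImage::bwlabel(metal)
  expect_equal(max(cc), 2)
  area <- sum(cc == 1) * 0.1^2
  expect_lt(abs(area - pi * 0.85^2) / (pi * 0.85^2), 0.05)
  # deterministic generation
  expect_identical(ph$labels, make_pelvis_phantom(cfg)$labels)
})

test_that("head phantom materials, rod area, and the rodless degenerate case", {
  cfg <- head_config(n_xy = 512, spacing = 0.05, z_half = 0.2)
  ph <- make_head_phantom(cfg)
  expect_setequal(ph$materials, c("air", "soft_tissue", "gypsum", "cerrobend"))
  metal <- slice_mask(oblique_slice(ph, 0), "cerrobend")
  cc <- EBImage::bwlabel(metal)
  expect_equal(max(cc), 2)
  area <- sum(cc == 1) * 0.05^2
  expect_lt(abs(area - pi * 0.6^2) / (pi * 0.6^2), 0.05)

  bald <- make_head_phantom(head_config(n_xy = 64, spacing = 0.4,
                                        z_half = 0.8, n_rods = 0))
  expect_false("cerrobend" %in% bald$materials)
})

test_that("invalid rod placements are rejected", {
  cfg <- pelvis_config(n_xy = 64, spacing = 0.6, z_half = 1.2)
  cfg$rods[[1]]$center <- c(-17, 0)
  expect_error(make_pelvis_phantom(cfg), "outside the body")
  cfg2 <- pelvis_config(n_xy = 64, spacing = 0.6, z_half = 1.2)
  cfg2$rods[[2]]$center <- cfg2$rods[[1]]$center + c(1, 0)
  expect_error(make_pelvis_phantom(cfg2), "overlap")
})

test_that("slicing at tilt zero is exactly the axial extraction", {
  ph <- make_pelvis_phantom(pelvis_config(n_xy = 128, spacing = 0.4,
                                          z_half = 2))
  sl <- oblique_slice(ph, 0, z0 = 0)
  k <- (dim(ph$labels)[3] + 1) / 2
  expect_identical(sl$labels, ph$labels[, , k])
  # z0 on another grid plane
  sl2 <- oblique_slice(ph, 0, z0 = 0.8)
  expect_identical(sl2$labels, ph$labels[, , k + 2])
})

test_that("oblique cut of a sphere is a circle of the sphere radius", {
  n <- 101; px <- 0.1; R <- 3
  co <- tiltmar:::pixel_coords(n, n, px)
  labs <- array(1L, dim = c(n, n, n))
  for (k in seq_len(n)) {
    z <- (k - (n + 1) / 2) * px
    labs[, , k][outer(co$y, co$x,
                      function(y, x) x^2 + y^2 + z^2 <= R^2)] <- 2L
  }
  ph <- voxel_phantom(labs, c(px, px, px), c("air", "water"))
  sl <- oblique_slice(ph, 15, z0 = 0)
  area <- sum(sl$labels == 2L) * px^2
  r_eq <- sqrt(area / pi)
  expect_lt(abs(r_eq - R), px)
})

test_that("metal cross-section under tilt stays within the foreshortening bound", {
  cfg <- pelvis_config(n_xy = 256, spacing = 0.2, z_half = 4,
                       rod_z_left = c(-4, 4), rod_z_right = c(-4, 4))
  ph <- make_pelvis_phantom(cfg)
  a0 <- sum(slice_mask(oblique_slice(ph, 0), cfg$metal))
  for (tilt in c(5, 10, 15)) {
    at <- sum(slice_mask(oblique_slice(ph, tilt), cfg$metal))
    bound <- a0 / cos(tilt * pi / 180) + 4 * sqrt(a0)  # one-voxel rim
    expect_lte(at, bound)
    expect_gte(at, a0 - 4 * sqrt(a0))
  }
})

test_that("10-degree tilt separates the pelvis rods: no ray meets both", {
  ph <- make_pelvis_phantom(pelvis_config(n_xy = 256, spacing = 0.2))
  geom <- fan_geometry(400, 1100, 720, 365, 170)
  ray_overlap <- function(slice) {
    metal <- slice_mask(slice, metal_materials(slice))
    cc <- EBImage::bwlabel(metal)
    if (max(cc) < 2) return(FALSE)
    traces <- lapply(seq_len(max(cc)), function(k)
      metal_trace(structure(list(values = cc == k), class = "metal_mask"),
                  geom, slice$spacing)$values)
    any(traces[[1]] & traces[[2]])
  }
  expect_true(ray_overlap(oblique_slice(ph, 0)))   # the artifact mechanism
  expect_false(ray_overlap(oblique_slice(ph, 10)))
})

test_that("cutting plane outside the grid raises an error", {
  ph <- make_pelvis_phantom(pelvis_config(n_xy = 64, spacing = 0.6,
                                          z_half = 1.2))
  expect_error(oblique_slice(ph, 0, z0 = 50), "misses")
  expect_error(oblique_slice(ph, 45), "tilt_deg")
})
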