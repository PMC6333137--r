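test_that("metal segmentation thresholds and closes the mask", {
  img <- recon_image(matrix(0.2, 40, 40), 0.1)
  expect_false(any(segment_metal(img, 1.2)$values))
  expect_warning(segment_metal(img, 1.2, expect_metal = TRUE), "no pixel")

  v <- matrix(0.2, 40, 40)
  blob <- disk_mask(40, 0.1, 0.8, 0, 0.3) | disk_mask(40, 0.1, -0.8, 0, 0.3)
  v[blob] <- 3
  v[12, 12] <- 3                       # isolated speck survives closing
  v[disk_mask(40, 0.1, 0.8, 0, 0.1)] <- 0.5  # hole inside a blob
  m <- segment_metal(recon_image(v, 0.1), 1.2)
  expect_true(all(m$values[blob]))     # closing filled the hole
})

test_that("metal trace geometry: empty, central rod, bilateral overlap", {
  geom <- fan_geometry(400, 1100, 36, 91, 120)
  empty <- structure(list(values = matrix(FALSE, 48, 48)),
                     class = "metal_mask")
  expect_false(any(metal_trace(empty, geom, 0.4)$values))

  rod <- structure(list(values = disk_mask(48, 0.4, 0, 0, 0.8)),
                   class = "metal_mask")
  tr <- metal_trace(rod, geom, 0.4)
  expect_true(all(tr$values[, 46]))   # central channel hit at every view

  left <- structure(list(values = disk_mask(48, 0.4, -6, 0, 0.8)),
                    class = "metal_mask")
  right <- structure(list(values = disk_mask(48, 0.4, 6, 0, 0.8)),
                     class = "metal_mask")
  tl <- metal_trace(left, geom, 0.4)$values
  tr2 <- metal_trace(right, geom, 0.4)$values
  expect_true(any(tl & tr2))  # lateral views see both rods in one ray

  # channel dilation widens the trace
  wide <- metal_trace(rod, geom, 0.4, dilate_channels = 2)
  expect_gt(sum(wide$values), sum(tr$values))
})

test_that("linear inpainting restores a smooth band and touches nothing else", {
  geom <- fan_geometry(400, 1100, 72, 181, 120)
  sino <- disk_sinogram(geom = geom)
  trace <- structure(list(values = matrix(FALSE, 72, 181)),
                     class = "trace_mask")
  expect_identical(inpaint_linear(sino, trace)$values, sino$values)

  trace$values[, 88:94] <- TRUE
  inp <- inpaint_linear(sino, trace)
  expect_identical(inp$values[!trace$values], sino$values[!trace$values])
  err <- abs(inp$values[, 88:94] - sino$values[, 88:94])
  expect_lt(max(err) / max(sino$values), 0.02)

  full <- trace; full$values[3, ] <- TRUE
  expect_error(inpaint_linear(sino, full), "entire view")
  edge <- structure(list(values = matrix(FALSE, 72, 181)),
                    class = "trace_mask")
  edge$values[, 1:4] <- TRUE
  expect_error(inpaint_linear(sino, edge), "neighbour")
})

test_that("LI-MAR with an empty trace is plain FBP, bitwise", {
  geom <- fan_geometry(400, 1100, 72, 181, 120)
  sino <- disk_sinogram(geom = geom)
  grid <- recon_grid(96, 0.2)
  trace <- structure(list(values = matrix(FALSE, 72, 181)),
                     class = "trace_mask")
  expect_identical(limar(sino, trace, grid)$values, fbp(sino, grid)$values)
})

test_that("NMAR prior flattens classes by the stated rules", {
  v <- matrix(0.2, 30, 30)
  v[1:5, ] <- 0.01            # air
  v[10:12, ] <- 0.6           # bone
  v[20, 20] <- 0.25
  metal <- structure(list(values = matrix(FALSE, 30, 30)),
                     class = "metal_mask")
  metal$values[25, 25] <- TRUE
  v[25, 25] <- 4
  img <- recon_image(v, 0.1)
  pr <- build_prior(img, metal)
  soft_val <- median(v[v >= 0.08 & v < 0.45 & !metal$values])
  expect_true(all(pr$values[1:5, ] == 0))
  expect_identical(pr$values[10:12, ], v[10:12, ])
  expect_equal(pr$values[20, 20], soft_val)
  expect_equal(pr$values[25, 25], soft_val)
  expect_error(build_prior(img, metal, cls = c(air = 1, bone = 0.5)),
               "increasing")

  allair <- recon_image(matrix(0.0, 10, 10), 0.1)
  emptym <- structure(list(values = matrix(FALSE, 10, 10)),
                      class = "metal_mask")
  expect_true(all(build_prior(allair, emptym)$values == 0))
})

test_that("NMAR: empty-trace identity, locality, and self-consistent restoration", {
  geom <- fan_geometry(400, 1100, 72, 181, 120)
  grid <- recon_grid(96, 0.2)
  truth <- disk_mask(96, 0.2, radius = 6) * 0.2
  sino <- forward_project(truth, geom, pixel_cm = 0.2)
  prior <- recon_image(truth, 0.2)
  trace <- structure(list(values = matrix(FALSE, 72, 181)),
                     class = "trace_mask")
  expect_identical(nmar(sino, trace, prior, grid)$values,
                   fbp(sino, grid)$values)

  trace$values[, 85:97] <- TRUE
  ps <- virtual_sinogram(prior, geom)
  inp <- inpaint_normalized(sino, trace, ps)
  expect_identical(inp$values[!trace$values], sino$values[!trace$values])
  # prior equal to the truth: normalized profile is flat, restoration exact
  err <- abs(inp$values[trace$values] - sino$values[trace$values])
  expect_lt(max(err) / max(sino$values), 0.02)
})
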