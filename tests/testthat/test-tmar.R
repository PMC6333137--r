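test_that("Gaussian denoising: identity, DC preservation, impulse response", {
  img <- recon_image(matrix(rnorm(64 * 64), 64, 64), 0.1)
  expect_identical(denoise(img, 0), img)
  flat <- matrix(3.7, 32, 32)
  expect_equal(denoise(flat, 2), flat, tolerance = 1e-12)
  imp <- matrix(0, 33, 33); imp[17, 17] <- 1
  out <- denoise(imp, 1)
  r <- ceiling(4 * 1)
  k <- exp(-(-r:r)^2 / 2); k <- k / sum(k)
  expect_equal(out[17, 17], k[r + 1]^2, tolerance = 1e-6)
  expect_error(denoise(imp, -1), "sigma")
})

test_that("artifact splitting is the elementwise scan difference", {
  a <- recon_image(matrix(runif(100), 10, 10), 0.1)
  b <- recon_image(matrix(runif(100), 10, 10), 0.1)
  expect_true(all(artifact_split(a, a)$values == 0))
  shifted <- recon_image(a$values + 0.3, 0.1)
  expect_equal(artifact_split(shifted, a)$values,
               matrix(0.3, 10, 10), tolerance = 1e-12)
  expect_equal(artifact_split(a, b)$values, -artifact_split(b, a)$values)
  expect_error(artifact_split(a, recon_image(matrix(0, 5, 5), 0.1)),
               "dimensions")
  hu <- recon_image(matrix(0, 10, 10), 0.1, units = "HU")
  expect_error(artifact_split(a, hu), "unit mismatch")
})

test_that("modified SSIM map: self-similarity, anticorrelation, bounds", {
  set.seed(1)
  x <- matrix(rnorm(30 * 30), 30, 30)
  p <- ssim_params(patch = 5)
  self <- modified_ssim_map(x, x, p)
  expect_true(all(abs(self$values - 1) < 1e-9))
  anti <- modified_ssim_map(x, -x, ssim_params(c2 = 1e-12, c3 = 1e-12))
  expect_true(all(anti$values < -1 + 1e-6))
  for (k in 1:5) {
    a <- matrix(rnorm(25 * 25), 25, 25)
    b <- matrix(rnorm(25 * 25), 25, 25)
    m <- modified_ssim_map(a, b, p)
    expect_true(all(abs(m$values) <= 1 + 1e-9))
  }
  expect_error(ssim_params(patch = 4), "odd")
  expect_error(modified_ssim_map(matrix(0, 3, 3), matrix(0, 3, 3),
                                 ssim_params(patch = 5)), "patch")
})

test_that("SSIM map equals the scalar per-patch oracle away from borders", {
  set.seed(2)
  x <- matrix(rnorm(11 * 11), 11, 11)
  y <- matrix(rnorm(11 * 11), 11, 11)
  p <- ssim_params(patch = 5, c2 = 0.03^2, c3 = 0.03^2 / 2)
  m <- modified_ssim_map(x, y, p)
  want <- oracle_ssim_patch(as.numeric(x[4:8, 4:8]), as.numeric(y[4:8, 4:8]),
                            c2 = 0.03^2, c3 = 0.03^2 / 2)
  expect_equal(m$values[6, 6], want, tolerance = 1e-12)
})

test_that("correlation maps follow the sign convention on a one-sided streak", {
  fx <- streak_fixture()
  base <- fx$tilt$values
  streaky <- fx$ori$values
  art <- artifact_split(fx$ori, fx$tilt)
  maps <- correlation_maps(streaky, base, art)
  streak_px <- abs(art$values) > 0.05
  expect_gt(mean(maps$c_ori$values[streak_px]),
            mean(maps$c_tilt$values[streak_px]))

  # swapping the scans swaps the two maps
  art_sw <- artifact_split(fx$tilt, fx$ori)
  maps_sw <- correlation_maps(base, streaky, art_sw)
  expect_equal(maps_sw$c_ori$values, maps$c_tilt$values, tolerance = 1e-12)
  expect_equal(maps_sw$c_tilt$values, maps$c_ori$values, tolerance = 1e-12)

  # degenerate identical pair: both maps defined and equal
  z <- artifact_split(fx$tilt, fx$tilt)
  mz <- correlation_maps(base, base, z)
  expect_equal(mz$c_ori$values, mz$c_tilt$values)

  bad <- art; bad$values <- art$values + 0.5
  expect_error(correlation_maps(streaky, base, bad), "difference")
})

test_that("fusion selects per pixel with ties to the tilted scan", {
  set.seed(3)
  n <- 20
  ori <- recon_image(matrix(runif(n * n), n, n), 0.1)
  tlt <- recon_image(matrix(runif(n * n), n, n), 0.1)
  lo <- structure(list(values = matrix(0, n, n)), class = "correlation_map")
  hi <- structure(list(values = matrix(1, n, n)), class = "correlation_map")
  expect_identical(fuse(ori, tlt, lo, hi)$fused$values, ori$values)
  expect_identical(fuse(ori, tlt, hi, hi)$fused$values, tlt$values)

  co <- matrix(runif(n * n), n, n)
  ct <- matrix(runif(n * n), n, n)
  ct[1:5, ] <- co[1:5, ]   # forced ties
  res <- fuse(ori, tlt, structure(list(values = co), class = "correlation_map"),
              structure(list(values = ct), class = "correlation_map"))
  member <- res$fused$values == ori$values | res$fused$values == tlt$values
  expect_true(all(member))
  expect_identical(res$fused$values[1:5, ], tlt$values[1:5, ])
  expect_identical(res$fused$values[res$mask], ori$values[res$mask])
  expect_error(fuse(ori, recon_image(matrix(0, 5, 5), 0.1), lo, hi),
               "dimensions")
})

test_that("T-MAR pipeline: degenerate pair, intermediates, swap behaviour", {
  fx <- streak_fixture(n = 64)
  p <- tmar_params(sigma = 0.5, exclude_metal = FALSE,
                   registration_check = FALSE)
  same <- tmar_pipeline(fx$ref, fx$ref, p)
  expect_identical(same$fused$values, fx$ref$values)
  expect_equal(mape(same$fused, fx$ref, fx$roi), 0)
  expect_false(any(same$mask))   # ties everywhere -> tilted input

  res <- tmar_pipeline(fx$ori, fx$tilt, p)
  expect_s3_class(res$art, "artifact_map")
  expect_true(all(res$fused$values == fx$ori$values |
                    res$fused$values == fx$tilt$values))
  # fusing complementary streaks beats both inputs
  expect_lt(mape(res$fused, fx$ref, fx$roi),
            min(mape(fx$ori, fx$ref, fx$roi), mape(fx$tilt, fx$ref, fx$roi)))

  # swapping the roles changes picks only at ties
  sw <- tmar_pipeline(fx$tilt, fx$ori, p)
  ties <- res$c_ori$values == res$c_tilt$values
  expect_equal(sw$fused$values[!ties], res$fused$values[!ties])
})

test_that("metal pixels are copied from the ordinary scan", {
  fx <- streak_fixture(n = 64)
  ori <- fx$ori; tlt <- fx$tilt
  metal_px <- disk_mask(64, 0.1, 1, 0, 0.5)
  ori$values[metal_px] <- 5    # implant present in the ordinary scan
  tlt$values[metal_px] <- 4.5
  res <- tmar_pipeline(ori, tlt, tmar_params(sigma = 0.5,
                                             exclude_metal = TRUE,
                                             metal_threshold = 2,
                                             registration_check = FALSE))
  expect_true(all(res$mask[metal_px]))
  expect_identical(res$fused$values[metal_px], ori$values[metal_px])
})

test_that("AT-MAR with stage 2 disabled reproduces T-MAR bitwise", {
  fx <- streak_fixture(n = 64)
  p <- tmar_params(sigma = 0.5, exclude_metal = FALSE,
                   registration_check = FALSE)
  one <- atmar_pipeline(fx$ori, fx$tilt, p, stages = 1)
  ref <- tmar_pipeline(fx$ori, fx$tilt, p)
  expect_identical(one$fused$values, ref$fused$values)
  expect_identical(one$mask, ref$mask)
})

test_that("AT-MAR second pass against a clean augment image", {
  fx <- streak_fixture(n = 64)
  p <- tmar_params(sigma = 0.5, exclude_metal = FALSE,
                   registration_check = FALSE)
  res <- atmar_pipeline(fx$ori, fx$tilt, p, augment = fx$ref)
  expect_s3_class(res$stage1, "mar_result")
  # stage 2 with an artifact-free augment cannot be worse than stage 1
  expect_lte(mape(res$fused, fx$ref, fx$roi),
             mape(res$stage1$fused, fx$ref, fx$roi) + 1)
  expect_error(atmar_pipeline(fx$ori, fx$tilt, p), "geom")
})
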