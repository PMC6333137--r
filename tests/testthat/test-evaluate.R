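test_that("MAPE closed forms", {
  ref <- recon_image(matrix(0.2, 8, 8), 0.1)
  roi <- roi_set(list(all = matrix(TRUE, 8, 8)))
  expect_equal(mape(ref, ref, roi), 0)
  up <- recon_image(ref$values * 1.1, 0.1)
  expect_equal(mape(up, ref, roi), 10, tolerance = 1e-9)

  # alternating +/- 5% on a 4-pixel ROI
  ref4 <- recon_image(matrix(0.2, 2, 2), 0.1)
  img4 <- recon_image(matrix(0.2 * c(1.05, 0.95, 1.05, 0.95), 2, 2), 0.1)
  expect_equal(mape(img4, ref4, roi_set(list(m = matrix(TRUE, 2, 2)))), 5,
               tolerance = 1e-9)

  # scale contravariance
  for (a in c(0.5, 2, 3.7)) {
    expect_equal(mape(recon_image(a * ref$values, 0.1), ref, roi),
                 100 * abs(a - 1), tolerance = 1e-9)
  }

  zero <- recon_image(matrix(0, 8, 8), 0.1)
  expect_error(mape(ref, zero, roi), "zero")
  expect_error(mape(ref, recon_image(matrix(1, 4, 4), 0.1), roi),
               "dimensions")
})

test_that("ROI sets validate their masks", {
  expect_error(roi_set(list()), "at least one")
  expect_error(roi_set(list(a = matrix(FALSE, 3, 3))), "empty")
  r <- roi_set(list(matrix(TRUE, 3, 3)))
  expect_equal(names(r$masks), "roi1")
})

test_that("default ROI excludes metal surroundings and class borders", {
  cfg <- pelvis_config(n_xy = 256, spacing = 0.2, z_half = 0.4)
  ph <- make_pelvis_phantom(cfg)
  sl <- oblique_slice(ph, 0)
  roi <- default_roi(sl)
  m <- roi$masks$soft_tissue
  metal <- slice_mask(sl, cfg$metal)
  grown <- as.matrix(EBImage::dilate(metal * 1, EBImage::makeBrush(7, "box"))) > 0.5
  expect_false(any(m & grown))
  expect_false(any(m & !slice_mask(sl, "soft_tissue") &
                     !slice_mask(sl, "adipose")))
  expect_gt(sum(m), 1000)
})

test_that("corridor ROI sits between the implants, inside soft tissue", {
  cfg <- pelvis_config(n_xy = 256, spacing = 0.2, z_half = 0.4)
  sl <- oblique_slice(make_pelvis_phantom(cfg), 0)
  roi <- roi_between_metals(sl)
  expect_named(roi$masks, "corridor")
  m <- roi$masks$corridor
  co <- tiltmar:::pixel_coords(256, 256, 0.2)
  xs <- range(co$x[which(m, arr.ind = TRUE)[, 2]])
  expect_gt(xs[1], -7.5)  # strictly between the rod centres
  expect_lt(xs[2], 7.5)
  # falls back to the full mask when there is one rod or none
  cfg1 <- cfg; cfg1$rods <- cfg$rods[1]
  roi1 <- roi_between_metals(oblique_slice(make_pelvis_phantom(cfg1), 0))
  expect_named(roi1$masks, "soft_tissue")
})

test_that("method comparison reports sorted MAPEs deterministically", {
  ref <- recon_image(matrix(0.2, 8, 8), 0.1)
  roi <- roi_set(list(all = matrix(TRUE, 8, 8)))
  methods <- list(worse = recon_image(ref$values * 1.2, 0.1),
                  best = ref,
                  mid = recon_image(ref$values * 1.1, 0.1))
  rep <- compare_methods(methods, ref, roi)
  expect_s3_class(rep, "eval_report")
  expect_equal(rep$method, c("best", "mid", "worse"))
  expect_equal(rep$mape_pct[1], 0)

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_report(rep, f1)
  write_report(compare_methods(methods, ref, roi), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  single <- compare_methods(list(only = ref), ref, roi)
  expect_equal(nrow(single), 1)
  expect_equal(single$mape_pct, 0)
  expect_error(compare_methods(list(ref), ref, roi), "named")
})
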