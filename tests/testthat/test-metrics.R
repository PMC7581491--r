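test_that("boundary errors follow the sign convention and restrict to valid range", {
  truth <- boundary_set(rep(10, 20), rep(30, 20), valid_start = 2,
                        valid_end = 17, height_px = 50)
  expect_equal(boundary_errors(truth, truth)$mae, c(0, 0))
  # prediction one row lower (larger row index) everywhere: ME = +1
  pred <- boundary_set(rep(11, 20), rep(31, 20), height_px = 50)
  be <- boundary_errors(pred, truth)
  expect_equal(be$mae, c(1, 1))
  expect_equal(be$me, c(1, 1))
  expect_equal(be$n, c(16, 16))                   # valid columns only
  # mixed +-1 errors: MAE 1, ME 0
  ilm <- rep(10, 20) + rep(c(1, -1), 10)
  pm <- boundary_set(ilm, rep(30, 20), height_px = 50)
  bm <- boundary_errors(pm, truth)
  expect_equal(bm$mae[1], 1)
  expect_equal(bm$me[1], 0)
  # swapping prediction and truth flips ME, keeps MAE
  b1 <- boundary_set(rep(12, 20), rep(33, 20))
  f <- boundary_errors(b1, truth); r <- boundary_errors(truth, b1)
  expect_equal(f$mae, r$mae)
  expect_equal(f$me, -r$me)
  expect_error(boundary_errors(boundary_set(1:5, 6:10), truth), "width")
})

test_that("fold error tables average per boundary and metric", {
  t1 <- boundary_errors(boundary_set(rep(11, 8), rep(31, 8)),
                        boundary_set(rep(10, 8), rep(30, 8)))
  t2 <- boundary_errors(boundary_set(rep(12, 8), rep(32, 8)),
                        boundary_set(rep(10, 8), rep(30, 8)))
  avg <- average_fold_errors(list(t1, t2))
  expect_equal(avg$mae, c(1.5, 1.5))
  expect_identical(average_fold_errors(list(t1, t1))$mae, t1$mae)
  # random tables: mean matches direct recomputation
  set.seed(11)
  tabs <- replicate(6, {
    t1$mae <- runif(2); t1$me <- rnorm(2); t1
  }, simplify = FALSE)
  avg6 <- average_fold_errors(tabs)
  expect_equal(avg6$mae, rowMeans(sapply(tabs, `[[`, "mae")))
  expect_equal(avg6$me, rowMeans(sapply(tabs, `[[`, "me")))
})

test_that("hard dice overlap is exact on constructed maps", {
  a <- matrix(c(0, 1, 2, 2), 2, 2)
  expect_equal(unname(dice_overlap(a, a)["overall"]), 100)
  # disjoint single-class maps
  d1 <- matrix(0L, 2, 2); d2 <- matrix(1L, 2, 2)
  per <- dice_overlap(d1, d2)
  expect_equal(unname(per["class0"]), 0)
  expect_equal(unname(per["class1"]), 0)
  expect_equal(unname(per["class2"]), 100)        # empty in both: agreement
  # |A| = 2, |B| = 2, |A intersect B| = 1 for class 1 -> 50%
  p1 <- matrix(c(1, 1, 0, 0), 2, 2)
  p2 <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(unname(dice_overlap(p1, p2)["class1"]), 50)
  expect_error(dice_overlap(matrix(0, 2, 2), matrix(0, 3, 3)), "mismatch")
})

test_that("thickness maps convert rows to microns with the scan geometry", {
  b <- lapply(1:5, function(s) boundary_set(rep(20, 10), rep(120, 10),
                                            height_px = 200))
  tm <- thickness_map(b, 3.9, 5.7, 119)
  expect_true(all(tm$thickness_um == 100 * 3.9))  # 390 um
  expect_equal(dim(tm$thickness_um), c(5L, 10L))
  expect_equal(diff(tm$x_mm)[1], 5.7 / 1000)
  expect_equal(diff(tm$y_mm)[1], 119 / 1000)
  bz <- lapply(1:5, function(s) boundary_set(rep(20, 10), rep(20, 10)))
  expect_true(all(thickness_map(bz, 3.9, 5.7, 119)$thickness_um == 0))
  bneg <- b
  bneg[[1]] <- boundary_set(rep(30, 10), rep(10, 10), validate = FALSE)
  expect_error(thickness_map(bneg, 3.9, 5.7, 119), "negative")
})

test_that("thickness map reproduces the generator's analytic profile", {
  cfg <- phantom_config(n_flecks = 0, speckle_looks = 0, n_shadows = 0)
  s <- generate_boundary_surfaces(cfg, rng_seed = 13)
  b <- lapply(seq_len(cfg$n_scans), function(k)
    boundary_set(s$ilm[k, ], s$rpe[k, ], height_px = cfg$height_px))
  tm <- thickness_map(b, cfg$axial_res_um, cfg$lateral_res_um,
                      cfg$scan_spacing_um)
  expect_equal(tm$thickness_um, s$thickness_um, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("ETDRS subfields partition the disc and integrate volume", {
  # fine clinical geometry: 61 scans x 119 um, 1536 columns x 5.7 um
  b <- lapply(1:61, function(s) boundary_set(rep(0, 1536),
                                             rep(100 / 3.9, 1536)))
  tm <- thickness_map(b, 3.9, 5.7, 119)
  st <- etdrs_stats(tm)
  expect_equal(nrow(st), 9)
  expect_true(all(abs(st$mean_um - 100) < 1e-9))
  # partition: subfield volumes sum exactly to the direct disc volume
  expect_equal(sum(st$volume_mm3), macular_volume(tm), tolerance = 1e-12)
  # constant 100 um: total volume = 0.1 mm * pi * (3 mm)^2 within 1%
  expect_equal(attr(st, "total_volume_mm3"), 0.1 * pi * 9, tolerance = 0.01)
  # central subfield area ~ pi (0.5)^2 within discretisation
  expect_equal(st$area_mm2[1], pi * 0.25, tolerance = 0.02)
  # rings partition into quadrants of roughly equal area
  inner <- st$area_mm2[2:5]
  expect_lt(diff(range(inner)) / mean(inner), 0.05)
  # insufficient coverage is rejected with a report
  tm_small <- thickness_map(b[1:10], 3.9, 5.7, 119)
  expect_error(etdrs_stats(tm_small), "cover")
})

test_that("ETDRS stats on phantom ground truth match the generator volume", {
  cfg <- phantom_config(severity = 0.5)
  s <- generate_boundary_surfaces(cfg, rng_seed = 17)
  b <- lapply(seq_len(cfg$n_scans), function(k)
    boundary_set(s$ilm[k, ], s$rpe[k, ], height_px = cfg$height_px))
  tm <- thickness_map(b, cfg$axial_res_um, cfg$lateral_res_um,
                      cfg$scan_spacing_um)
  st <- etdrs_stats(tm)
  expect_equal(attr(st, "total_volume_mm3"),
               octseg:::surface_macular_volume(s), tolerance = 1e-12)
})

test_that("bland-altman reports mean difference and 1.96 SD limits", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ba0$mean, 0)
  expect_equal(c(ba0$lower, ba0$upper), c(0, 0))
  ba5 <- bland_altman(c(6, 7, 8), c(1, 2, 3))
  expect_equal(ba5$mean, 5)
  expect_equal(c(ba5$lower, ba5$upper), c(5, 5))
  # d = {-1, +1}: SD = sqrt(2), limits at +-1.96 sqrt(2)
  ba <- bland_altman(c(0, 2), c(1, 1))
  expect_equal(ba$mean, 0)
  expect_equal(ba$sd, sqrt(2))
  expect_equal(ba$lower, -1.96 * sqrt(2), tolerance = 1e-9)
  expect_equal(ba$upper, 1.96 * sqrt(2), tolerance = 1e-9)
  expect_lte(ba$lower, ba$mean); expect_gte(ba$upper, ba$mean)
  expect_error(bland_altman(1, 1), "n >= 2")
  expect_error(bland_altman(1:3, 1:4), "paired")
})
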