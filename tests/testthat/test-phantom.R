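test_that("surfaces are deterministic, ordered and slope-bounded", {
  cfg <- phantom_config()
  s1 <- generate_boundary_surfaces(cfg, rng_seed = 11)
  s2 <- generate_boundary_surfaces(cfg, rng_seed = 11)
  expect_identical(s1$ilm, s2$ilm)
  expect_identical(s1$rpe, s2$rpe)
  expect_true(all(s1$ilm <= s1$rpe))
  expect_true(all(s1$ilm >= 0) && all(s1$rpe <= cfg$height_px - 1))
  slopes <- abs(cbind(diff(t(s1$ilm)), diff(t(s1$rpe))))
  expect_lte(max(slopes), 1)
  s3 <- generate_boundary_surfaces(cfg, rng_seed = 12)
  expect_false(identical(s1$ilm, s3$ilm))
})

test_that("constant-thickness configuration gives exactly constant thickness", {
  cfg <- clean_phantom_config(retina_um = 100 * 15.1)   # 100 px
  cfg$rpe_level_frac <- 0.9                              # keep ilm in frame
  s <- generate_boundary_surfaces(cfg, rng_seed = 1)
  expect_equal(as.numeric(s$rpe - s$ilm), rep(100, length(s$rpe)),
               tolerance = 1e-12)
})

test_that("foveal pit thins the centre by the configured depth", {
  depth_px <- 30
  cfg <- clean_phantom_config(pit_depth_um = depth_px * 15.1,
                              pit_fwhm_mm = 2, retina_um = 600)
  s <- generate_boundary_surfaces(cfg, rng_seed = 4)
  th <- s$rpe - s$ilm
  centre_scan <- (cfg$n_scans + 1) %/% 2
  centre_col <- cfg$width_px %/% 2
  # analytic pit profile: exp(-r^2 / (2 sigma^2)) with the generator's sigma
  sigma <- 2 / (2 * sqrt(2 * log(2)))
  x_mm <- (centre_col - (cfg$width_px + 1) / 2) * cfg$lateral_res_um / 1000
  y_mm <- (centre_scan - (cfg$n_scans + 1) / 2) * cfg$scan_spacing_um / 1000
  expected_drop <- depth_px * exp(-(x_mm^2 + y_mm^2) / (2 * sigma^2)) -
    depth_px * exp(-((-4.38)^2) / (2 * sigma^2))   # edge term ~ 0
  drop <- th[centre_scan, 1] - th[centre_scan, centre_col]
  expect_equal(drop, expected_drop, tolerance = 0.05)
  expect_equal(drop, depth_px, tolerance = 0.2)
})

test_that("impossible thickness parameters are rejected with a message", {
  cfg <- clean_phantom_config(retina_um = 50)
  cfg$severity <- 1
  cfg$n_lesions <- 1L
  cfg$lesion_loss_um <- 100                       # thinning exceeds thickness
  expect_error(generate_boundary_surfaces(cfg, 1), "ilm > rpe")
})

test_that("noise-free rendering paints exact region intensities", {
  cfg <- clean_phantom_config()
  s <- generate_boundary_surfaces(cfg, rng_seed = 2)
  b <- render_bscan(s, cfg, rng_seed = 1, slice = 3)
  px <- b$pixels
  ilm_f <- floor(s$ilm[3, ]); rpe_f <- floor(s$rpe[3, ])
  for (cc in c(1, 64, 200)) {
    col <- px[, cc]
    expect_true(all(col[seq_len(ilm_f[cc])] == cfg$int_vitreous))
    retina_rows <- (ilm_f[cc] + 1):(rpe_f[cc] - cfg$rpe_band_px)
    expect_true(all(col[retina_rows] == cfg$int_retina))
    band_rows <- (rpe_f[cc] - cfg$rpe_band_px + 1):rpe_f[cc]
    expect_true(all(col[band_rows] == cfg$int_rpe))
    chor_rows <- (rpe_f[cc] + 1):(rpe_f[cc] + cfg$choroid_px)
    expect_true(all(col[chor_rows] == cfg$int_choroid))
    expect_true(all(col[(rpe_f[cc] + cfg$choroid_px + 1):nrow(px)] ==
                      cfg$int_sclera))
  }
  # retina brighter than vitreous by construction
  retina_mask <- outer(seq_len(nrow(px)) - 1, ilm_f, `>=`) &
    outer(seq_len(nrow(px)) - 1, rpe_f, `<`)
  expect_gt(mean(px[retina_mask]), mean(px[!retina_mask & outer(
    seq_len(nrow(px)) - 1, ilm_f, `<`)]))
})

test_that("atrophy suppresses the RPE band by the severity-weighted factor", {
  cfg <- phantom_config(n_flecks = 0, speckle_looks = 0, n_shadows = 0,
                        pit_depth_um = 0, undulation_amp_px = 0,
                        n_lesions = 1L, lesion_width_px = 200L,
                        lesion_extent_mm = 6, severity = 0.6)
  s <- generate_boundary_surfaces(cfg, rng_seed = 7)
  slice <- which.max(apply(s$atrophy_w, 1, max))  # slice through the lesion
  b <- render_bscan(s, cfg, rng_seed = 1, slice = slice)
  aw <- s$atrophy_w[slice, ]
  rpe_f <- floor(s$rpe[slice, ])
  band_val <- vapply(seq_len(cfg$width_px),
                     function(cc) b$pixels[rpe_f[cc], cc], numeric(1))
  inside <- aw > 0.5 * max(aw)
  outside <- aw == 0
  expect_true(any(inside) && any(outside))
  # generator's own intensity model: band = int_rpe * (1 - severity * w)
  expect_equal(mean(band_val[inside]),
               mean(cfg$int_rpe * (1 - cfg$severity * aw[inside])),
               tolerance = 1e-10)
  expect_equal(mean(band_val[outside]), cfg$int_rpe, tolerance = 1e-10)
  expect_lt(mean(band_val[inside]), mean(band_val[outside]))
})

test_that("rendering is seed-deterministic", {
  cfg <- phantom_config()
  s <- generate_boundary_surfaces(cfg, rng_seed = 3)
  b1 <- render_bscan(s, cfg, rng_seed = 9, slice = 1)
  b2 <- render_bscan(s, cfg, rng_seed = 9, slice = 1)
  expect_identical(b1$pixels, b2$pixels)
  expect_true(min(b1$pixels) >= 0 && max(b1$pixels) <= 255)
})

test_that("cohort generation balances groups by median split", {
  cfg <- phantom_config(n_scans = 5L)
  co <- generate_cohort(12, scans_per_volume = 5, config = cfg, rng_seed = 2)
  grp <- vapply(co$participants, `[[`, character(1), "group")
  expect_equal(sum(grp == "low"), 6)
  expect_equal(sum(grp == "high"), 6)
  vols <- vapply(co$participants, `[[`, numeric(1), "baseline_volume_mm3")
  expect_true(max(vols[grp == "low"]) <= min(vols[grp == "high"]))
  # identical call is fully deterministic
  co2 <- generate_cohort(12, scans_per_volume = 5, config = cfg, rng_seed = 2)
  expect_identical(cohort_manifest(co), cohort_manifest(co2))
})

test_that("cohort generation rejects invalid requests", {
  expect_error(generate_cohort(12, scans_per_volume = 2), "ETDRS")
  expect_error(generate_cohort(7), "even")
})

test_that("ground-truth volume decreases monotonically with severity", {
  vols <- vapply(c(0.2, 0.5, 0.8), function(sev) {
    cfg <- phantom_config(severity = sev)
    octseg:::surface_macular_volume(generate_boundary_surfaces(cfg, 9))
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("constant-thickness ground-truth macular volume matches pi r^2 t", {
  cfg <- clean_phantom_config(retina_um = 250)
  s <- generate_boundary_surfaces(cfg, 1)
  v <- octseg:::surface_macular_volume(s)
  expect_equal(v, 0.25 * pi * 9, tolerance = 0.01)
})
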