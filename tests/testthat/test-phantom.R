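test_that("subject draws are deterministic and condition-calibrated", {
  s1 <- sample_subject(55, "baseline")
  s2 <- sample_subject(55, "baseline")
  expect_identical(s1, s2)
  # distribution of true CBF: mean 0.45 at baseline
  draws <- vapply(1:1000, function(i)
    sample_subject(10000 + i, "baseline")$cbf_true, numeric(1))
  expect_lt(abs(mean(draws) - 0.45), 0.01)
  expect_true(all(draws > 0.2))
  # paired acetazolamide draws run higher
  pairs <- vapply(1:100, function(i) {
    a <- sample_subject(20000 + i, "acz")$cbf_true
    b <- sample_subject(30000 + i, "baseline")$cbf_true
    a - b
  }, numeric(1))
  expect_gt(mean(pairs), 0)
  # acetazolamide arrives earlier and carries a larger local bolus area
  sa <- sample_subject(55, "acz")
  expect_equal(sa$area_boost, 1.15)
})

test_that("the bolus generator respects amplitude, delay and area scaling", {
  s <- sample_subject(56, "baseline")
  s0 <- s; s0$amplitude <- 0
  expect_true(all(generate_aif(s0)$value == 0))
  a <- generate_aif(s, delay = 0)
  a10 <- generate_aif(s, delay = 10)
  expect_equal(which.max(a10$value), which.max(a$value) + 10)
  # single dominant peak in the physiologic window once delayed
  la <- local_aif(s)
  expect_true(which.max(la$value) >= 15 && which.max(la$value) <= 60)
  expect_true(all(la$value >= 0))
  # area linear in amplitude scale
  expect_equal(sum(generate_aif(s, scale = 2)$value),
               2 * sum(a$value), tolerance = 1e-12)
})

test_that("noise-free, PSF-free rendering reproduces the frame-averaged carotid curve", {
  s <- sample_subject(57, "baseline")
  geom <- phantom_geometry(psf_fwhm_mm = 0)
  sc <- render_dynamic_image(s, geom, noise_scale = 0, seed = 1)
  idif <- extract_idif(sc$image, geom$carotid_mask)
  oracle <- rebin_to_schedule(local_aif(s), default_frame_schedule())
  expect_equal(idif$value, oracle$value, tolerance = 1e-12)
})

test_that("rendering is reproducible and partial volume orders the peaks", {
  s <- sample_subject(58, "baseline")
  geom <- phantom_geometry()
  a <- render_dynamic_image(s, geom, noise_scale = 0.5, seed = 9)
  b <- render_dynamic_image(s, geom, noise_scale = 0.5, seed = 9)
  expect_identical(a$image$voxels, b$image$voxels)
  idifs <- run_idif_pipeline(a$image, a$gm_mask, phantom_config())
  expect_gt(max(idifs$idif10$value), max(idifs$idif1000$value))
})

test_that("enough voxels carry carotid signal after the PSF", {
  geom <- phantom_geometry()
  blurred <- gauss_blur3d(geom$carotid_mask * 1.0,
                          geom$psf_fwhm_mm / 2.3548 / geom$voxel_size)
  expect_gte(sum(blurred > 1e-3), 2000)
  # carotid and grey matter are disjoint
  expect_false(any(geom$carotid_mask & geom$gm_mask))
})

test_that("the wrist measurement is a delayed dispersed copy with exact calibration", {
  s <- sample_subject(59, "baseline")
  # degenerate wrist: no extra delay, no dispersion, unit detector scale
  s0 <- s
  s0$wrist_delay <- s$brain_delay
  s0$wrist_tau <- 0
  s0$detector_scale <- 1
  s0$area_boost <- 1
  m0 <- generate_wrist_measurement(s0, noise_scale = 0, seed = 1)
  expect_equal(m0$counts$value, local_aif(s0)$value, tolerance = 1e-12)
  # calibration sample is the true concentration at 300 s
  m <- generate_wrist_measurement(s, noise_scale = 0, seed = 1)
  truth <- attr(m, "truth")
  expect_equal(m$cal_value, truth$value[truth$t == 300])
})

test_that("the blood pipeline inverts the wrist forward model", {
  s <- sample_subject(60, "baseline")
  m <- generate_wrist_measurement(s, noise_scale = 0, seed = 1)
  la <- tac_window(local_aif(s), 360)
  rec <- recover_aif(m, la)  # align against the true local curve
  rms <- sqrt(mean((rec$aif$value - la$value)^2)) / max(la$value)
  expect_lt(rms, 0.03)
  # recovered shift is the (negative, rounded) wrist-to-brain delay
  expect_equal(rec$shift, -round(s$wrist_delay - s$brain_delay),
               tolerance = 1)
})

test_that("cohorts are seed-reproducible with ground truth kept apart", {
  fx <- small_cohort()
  co <- fx$cohort
  expect_length(co$subjects, 6L)
  expect_named(co$subjects[[1]], c("baseline", "acz"))
  co2 <- generate_cohort(3, seed = 77)
  co3 <- generate_cohort(3, seed = 77)
  expect_identical(co2$subjects[[2]]$acz$image$voxels,
                   co3$subjects[[2]]$acz$image$voxels)
  co4 <- generate_cohort(3, seed = 78)
  expect_false(identical(co2$subjects[[2]]$acz$image$voxels,
                         co4$subjects[[2]]$acz$image$voxels))
  # leakage guard: processing never touches the truth element
  scan <- co2$subjects[[1]]$baseline
  blinded <- scan; blinded$truth <- NULL
  expect_equal(process_scan(blinded)$aif$value, process_scan(scan)$aif$value)
})

test_that("the full pipeline tracks true CBF across the cohort", {
  fx <- small_cohort()
  errs <- vapply(seq_along(fx$cohort$subjects), function(i) {
    truth <- fx$cohort$subjects[[i]]$baseline$truth$subject
    rec <- fx$records$baseline[[i]]
    fit <- fit_1tcm(rec$tissue, rec$aif)
    # wrist-AIF CBF absorbs the grey-matter partial-volume loss; compare
    # relative, not absolute
    fit$cbf / truth$cbf_true
  }, numeric(1))
  expect_lt(sd(errs) / mean(errs), 0.15)  # consistent scale across subjects
  expect_gt(mean(errs), 0.6)
})
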