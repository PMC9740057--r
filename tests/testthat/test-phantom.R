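test_that("phantom label map carries exactly the four labels, ROIs connected and disjoint", {
  ph <- tiny_phantom()
  lab <- ph$labels$labels
  expect_setequal(unique(as.vector(lab)), 0:3)
  for (l in 1:3) {
    roi <- lab == l
    expect_gt(sum(roi), 0)
    expect_true(is_connected_3d(roi))
  }
  # labels partition the grid, so tumor ROIs are disjoint by construction
  expect_error(build_phantom(c(8, 8, 4), "extracranial_pre"), "too small")
  expect_error(build_phantom(c(24, 24, 12), "no_such_preset"), "unknown preset")
})

test_that("presets attach the printed perfusion ground truth to their ROI", {
  gt_ex <- preset_ground_truth("extracranial_pre")
  expect_equal(gt_ex$extracranial$auc30_true, 0.067, tolerance = 1e-9)
  expect_equal(gt_ex$extracranial$auc300_true, 0.193, tolerance = 1e-9)
  expect_equal(gt_ex$extracranial$t2_ms, 128.2)
  expect_equal(gt_ex$extracranial$ce_t1_ms, 786.1)
  gt_in <- preset_ground_truth("intracranial_pre")
  expect_equal(gt_in$intracranial$auc30_true, 0.058, tolerance = 1e-9)
  # record invariants hold for every preset and ROI
  for (preset in preset_names()) {
    for (rec in preset_ground_truth(preset)) {
      expect_true(rec$t1_ms > rec$t2_ms && rec$t2_ms > 0)
      expect_true(rec$adc_mm2_per_s > 0)
      expect_true(rec$ce_t1_ms <= rec$t1_ms)
      expect_true(rec$auc300_true >= rec$auc30_true)
      expect_true(rec$auc30_true >= 0)
    }
  }
})

test_that("noiseless VFA simulation equals the SPGR closed form", {
  p <- acq_protocol()
  t1 <- array(c(800, 1500), c(2, 1, 1))
  m0 <- array(c(1000, 500), c(2, 1, 1))
  st <- simulate_vfa_series(t1, m0, p)
  for (k in seq_along(p$flip_angles_deg)) {
    expect_equal(st$volumes[, 1, 1, k],
                 spgr_signal(c(800, 1500), c(1000, 500), p$tr_ms,
                             p$flip_angles_deg[k]),
                 tolerance = 1e-12)
  }
  # T1 -> infinity limit: signal vanishes at every angle
  stinf <- simulate_vfa_series(array(1e9, c(1, 1, 1)),
                               array(1000, c(1, 1, 1)), p)
  expect_true(all(stinf$volumes < 1e-3))
  expect_error(simulate_vfa_series(array(0, c(1, 1, 1)),
                                   array(1, c(1, 1, 1)), p), "positive")
})

test_that("noiseless multi-echo and DWI simulations match their closed forms", {
  p <- acq_protocol(echo_times_ms = c(50, 100, 150))
  st <- simulate_multiecho_series(array(100, c(1, 1, 1)),
                                  array(1000, c(1, 1, 1)), p)
  expect_equal(st$volumes[1, 1, 1, 2], 1000 / exp(1), tolerance = 1e-12)
  expect_true(all(diff(st$volumes[1, 1, 1, ]) < 0))  # strict decay
  dw <- simulate_dwi_series(array(1e-3, c(1, 1, 1)),
                            array(1000, c(1, 1, 1)),
                            b_values = c(0, 1000))
  expect_identical(dw$volumes[1, 1, 1, 1], 1000)          # b = 0 identity
  expect_equal(dw$volumes[1, 1, 1, 2], 1000 / exp(1), tolerance = 1e-12)
})

test_that("seeded noise is reproducible and distinct across seeds", {
  p <- acq_protocol()
  t1 <- array(1000, c(4, 4, 2)); m0 <- array(1000, c(4, 4, 2))
  a <- simulate_vfa_series(t1, m0, p, noise_sd = 5, seed = 11)
  b <- simulate_vfa_series(t1, m0, p, noise_sd = 5, seed = 11)
  c <- simulate_vfa_series(t1, m0, p, noise_sd = 5, seed = 12)
  expect_identical(a$volumes, b$volumes)
  expect_false(identical(a$volumes, c$volumes))
  # Rician magnitude noise keeps signals non-negative
  expect_true(all(a$volumes >= 0))
})

test_that("noiseless DCE series has 100 frames and an exact SPGR baseline", {
  ph <- tiny_phantom()
  p <- acq_protocol()
  dce <- simulate_dce_series(ph$labels, ph$ground_truth, p)
  expect_identical(dim(dce$frames)[4], 100L)
  rec <- ph$ground_truth$extracranial
  vox <- which(ph$labels$labels == 3, arr.ind = TRUE)[1, ]
  base <- spgr_signal(rec$t1_ms, rec$m0, p$dce_tr_ms, p$dce_flip_deg)
  expect_equal(dce$frames[vox[1], vox[2], vox[3], 1:20], rep(base, 20),
               tolerance = 1e-9)
  # post-contrast frames rise above baseline in a perfused ROI
  expect_gt(max(dce$frames[vox[1], vox[2], vox[3], ]), base)
})

test_that("zero-amplitude curves give a flat noiseless dynamic series", {
  ph <- tiny_phantom()
  flat <- lapply(ph$ground_truth, function(rec) {
    rec$curve_params <- solve_curve_params(0, 0)
    rec
  })
  dce <- simulate_dce_series(ph$labels, flat, acq_protocol())
  v <- matrix(dce$frames, ncol = 100)
  expect_equal(v, v[, rep(1, 100)], tolerance = 1e-12)
  # a labelled ROI with no ground truth is refused
  expect_error(simulate_dce_series(ph$labels, flat["brain"], acq_protocol()),
               "missing ground truth")
})

test_that("ground-truth serialization round-trips losslessly", {
  gt <- preset_ground_truth("extracranial_1h")
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, f)
  back <- read_ground_truth(f)
  for (roi in names(gt)) {
    orig <- unclass(gt[[roi]])
    got <- unclass(back[[roi]])
    expect_identical(got$roi_label, orig$roi_label)
    for (fld in c("t1_ms", "t2_ms", "ce_t1_ms", "adc_mm2_per_s", "m0",
                  "auc30_true", "auc300_true")) {
      expect_identical(got[[fld]], orig[[fld]])
    }
    expect_identical(unlist(got$curve_params), unlist(orig$curve_params))
  }
})
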