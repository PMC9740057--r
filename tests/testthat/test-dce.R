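make_series <- function(mat, protocol = acq_protocol()) {
  # mat: nvox x 100 signal matrix arranged on an nvox x 1 x 1 grid
  dynamic_series(array(mat, c(nrow(mat), 1, 1, ncol(mat))),
                 frame_times(protocol), protocol$n_pre_frames, protocol)
}

test_that("baseline is the pre-frame mean with its temporal SD", {
  p <- acq_protocol()
  m <- matrix(500, 1, 100)
  bl <- estimate_baseline(make_series(m, p))
  expect_equal(bl$baseline$values[1, 1, 1], 500)
  expect_equal(bl$sd$values[1, 1, 1], 0)
  m2 <- matrix(100, 1, 100); m2[1, 1:20] <- rep(c(90, 110), 10)
  bl2 <- estimate_baseline(make_series(m2, p))
  expect_equal(bl2$baseline$values[1, 1, 1], 100)
  p2 <- acq_protocol(n_pre_frames = 1, n_post_frames = 99)
  expect_error(estimate_baseline(
    dynamic_series(array(1, c(1, 1, 1, 100)), frame_times(p2), 1, p2)),
    "pre-injection")
})

test_that("signal at baseline converts to zero concentration; r1 scales linearly", {
  p <- acq_protocol()
  t10 <- array(1200, c(1, 1, 1))
  base <- spgr_signal(1200, 800, p$dce_tr_ms, p$dce_flip_deg)
  series <- make_series(matrix(base, 1, 100), p)
  bl <- estimate_baseline(series)
  conc <- signal_to_concentration(series, bl$baseline, t10, p)
  expect_equal(as.vector(conc$conc), rep(0, 100), tolerance = 1e-10)
  # halving r1 doubles recovered concentration exactly (noiseless)
  ph <- tiny_phantom()
  dce <- simulate_dce_series(ph$labels, ph$ground_truth, p)
  blp <- estimate_baseline(dce)
  t10m <- phantom_parameter_map(ph, "t1")
  mask <- ph$labels$labels > 0
  c1 <- signal_to_concentration(dce, blp$baseline, t10m, p, mask = mask)
  p2 <- p; p2$r1_relaxivity <- p$r1_relaxivity / 2
  c2 <- signal_to_concentration(dce, blp$baseline, t10m, p2, mask = mask)
  expect_equal(c2$conc[mask], 2 * c1$conc[mask], tolerance = 1e-9)
})

test_that("forward-simulated series invert back to the true curve within 1e-6 mmol/L", {
  p <- acq_protocol()
  ph <- tiny_phantom()
  dce <- simulate_dce_series(ph$labels, ph$ground_truth, p)
  bl <- estimate_baseline(dce)
  conc <- signal_to_concentration(dce, bl$baseline,
                                  phantom_parameter_map(ph, "t1"), p,
                                  mask = ph$labels$labels > 0)
  tt <- frame_times(p)
  for (roi in c("brain", "intracranial", "extracranial")) {
    rec <- ph$ground_truth[[roi]]
    truth <- numeric(100)
    truth[tt > 0] <- tissue_concentration_curve(rec$curve_params, tt[tt > 0])
    vox <- which(ph$labels$labels == ROI_LABELS[[roi]], arr.ind = TRUE)[1, ]
    got <- conc$conc[vox[1], vox[2], vox[3], ]
    expect_lt(max(abs(got - truth)), 1e-6)
  }
})

test_that("AUC handles rectangles, edge interpolation, additivity and monotonicity", {
  flat <- data.frame(times_s = seq(0, 30, by = 1.5), conc_mM = 1)
  expect_equal(auc(flat, 30), 0.5)                   # 30 s x 1 mM = 0.5 mM*min
  # window edge between samples: interpolation reproduces the analytic area
  ramp <- data.frame(times_s = c(0, 28, 32), conc_mM = c(0, 28, 32))  # C = t
  expect_equal(auc(ramp, 30), (30^2 / 2) / 60, tolerance = 1e-12)
  # additivity of adjacent windows
  cp <- solve_curve_params(0.067, 0.193)
  tt <- seq(1.8, 286.2, by = 3.6)
  curve <- data.frame(times_s = tt,
                      conc_mM = tissue_concentration_curve(cp, tt))
  a300 <- auc(curve, 300, partial = "silent")
  expect_equal(a300, auc(curve, 30) +
                 auc(curve, 300, start_s = 30, partial = "silent"),
               tolerance = 1e-12)
  # monotone in window length and in pointwise scaling
  expect_gt(a300, auc(curve, 30))
  curve2 <- curve; curve2$conc_mM <- 2 * curve2$conc_mM
  expect_equal(auc(curve2, 30), 2 * auc(curve, 30), tolerance = 1e-12)
})

test_that("windows beyond the sampled support truncate with a warning", {
  tt <- seq(1.8, 286.2, by = 3.6)
  curve <- data.frame(times_s = tt, conc_mM = exp(-tt / 20))
  expect_warning(auc(curve, 300), "truncated")
  expect_error(auc(curve, 300, partial = "error"), "truncated")
  expect_silent(auc(curve, 300, partial = "silent"))
  # truncation at the last sample equals integrating to the last sample
  expect_equal(auc(curve, 300, partial = "silent"), auc(curve, 286.2),
               tolerance = 1e-12)
})

test_that("T1 ratio is 1 for identical maps and tracks scaling", {
  m <- array(1000, c(2, 2, 1))
  expect_equal(t1_ratio(m, m)$values, array(1, c(2, 2, 1)))
  expect_equal(t1_ratio(m / 2, m)$values, array(0.5, c(2, 2, 1)))
  pre <- parameter_map(array(c(1000, NA), c(2, 1, 1)), "ms",
                       array(c(TRUE, FALSE), c(2, 1, 1)))
  r <- t1_ratio(array(500, c(2, 1, 1)), pre)
  expect_true(r$mask[1, 1, 1])
  expect_false(r$mask[2, 1, 1])   # invalid denominator -> invalid voxel
})

test_that("pre-injection concentrations stay within the propagated noise floor", {
  p <- acq_protocol()
  ph <- tiny_phantom()
  dce <- simulate_dce_series(ph$labels, ph$ground_truth, p, noise_sd = 2,
                             seed = 21)
  bl <- estimate_baseline(dce)
  conc <- signal_to_concentration(dce, bl$baseline,
                                  phantom_parameter_map(ph, "t1"), p,
                                  mask = ph$labels$labels > 0)
  pre <- conc$conc[, , , 1:20]
  pre <- pre[is.finite(pre)]
  # pre-injection concentrations scatter around zero inside 3 noise SDs
  expect_gt(mean(abs(pre) < 3 * stats::sd(pre)), 0.99)
  expect_lt(abs(mean(pre)), 0.2 * stats::sd(pre))
})
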