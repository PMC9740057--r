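test_that("noiseless VFA round trip recovers T1 to 1e-6 relative", {
  p <- acq_protocol()
  for (t1_true in c(786.1, 1000, 1832.4, 2054.1)) {
    t1 <- array(t1_true, c(2, 2, 1)); m0 <- array(1000, c(2, 2, 1))
    fit <- fit_t1_vfa(simulate_vfa_series(t1, m0, p))
    expect_true(all(fit$t1$mask))
    expect_equal(fit$t1$values, t1, tolerance = 1e-6)
    expect_equal(fit$m0$values, m0, tolerance = 1e-6)
  }
})

test_that("noiseless multi-echo round trip recovers T2 to 1e-9 relative", {
  p <- acq_protocol()
  for (t2_true in c(100, 111.5, 128.2)) {
    t2 <- array(t2_true, c(2, 2, 1)); s0 <- array(1000, c(2, 2, 1))
    fit <- fit_t2(simulate_multiecho_series(t2, s0, p))
    expect_equal(fit$t2$values, t2, tolerance = 1e-9)
  }
  # two-echo closed form: T2 = (TE2 - TE1) / log(S1/S2)
  s1 <- 800; s2 <- 300
  stack <- signal_stack(array(c(s1, s2), c(1, 1, 1, 2)), c(20, 90),
                        axis = "echo_time_ms")
  fit <- fit_t2(stack)
  expect_equal(fit$t2$values[1, 1, 1], (90 - 20) / log(s1 / s2),
               tolerance = 1e-12)
})

test_that("ADC fitting matches closed forms, including the zero-diffusion case", {
  stack <- signal_stack(array(c(1000, 1000 / exp(1)), c(1, 1, 1, 2)),
                        c(0, 1000), axis = "b_value")
  expect_equal(fit_adc(stack)$adc$values[1, 1, 1], 1e-3, tolerance = 1e-12)
  # constant signal across b-values -> ADC exactly 0 (valid, not gated out)
  const <- signal_stack(array(500, c(1, 1, 1, 3)), c(0, 500, 1000),
                        axis = "b_value")
  fit <- fit_adc(const)
  expect_identical(fit$adc$values[1, 1, 1], 0)
  expect_true(fit$adc$mask[1, 1, 1])
  # three-b round trip
  adc <- array(0.8e-3, c(2, 1, 1)); s0 <- array(1000, c(2, 1, 1))
  f <- fit_adc(simulate_dwi_series(adc, s0, b_values = c(0, 500, 1000)))
  expect_equal(f$adc$values, adc, tolerance = 1e-9)
})

test_that("global signal scaling leaves T1/T2/ADC unchanged and scales M0/S0", {
  p <- acq_protocol()
  t1 <- array(c(900, 1400), c(2, 1, 1)); m0 <- array(1000, c(2, 1, 1))
  st <- simulate_vfa_series(t1, m0, p)
  st2 <- st; st2$volumes <- st$volumes * 7
  f1 <- fit_t1_vfa(st); f2 <- fit_t1_vfa(st2)
  expect_equal(f2$t1$values, f1$t1$values, tolerance = 1e-10)
  expect_equal(f2$m0$values, 7 * f1$m0$values, tolerance = 1e-10)
  t2m <- array(c(80, 120), c(2, 1, 1))
  me <- simulate_multiecho_series(t2m, m0, p)
  me2 <- me; me2$volumes <- me$volumes * 3
  g1 <- fit_t2(me); g2 <- fit_t2(me2)
  expect_equal(g2$t2$values, g1$t2$values, tolerance = 1e-10)
  expect_equal(g2$s0$values, 3 * g1$s0$values, tolerance = 1e-10)
})

test_that("degenerate voxels are flagged invalid, never raised as errors", {
  p <- acq_protocol()
  vols <- array(0, c(2, 1, 1, 9))
  vols[1, 1, 1, ] <- spgr_signal(1000, 1000, p$tr_ms, p$flip_angles_deg)
  st <- signal_stack(vols, p$flip_angles_deg, "flip_angle_deg", p)
  fit <- fit_t1_vfa(st, tr_ms = p$tr_ms,
                    mask = array(TRUE, c(2, 1, 1)))
  expect_true(fit$t1$mask[1, 1, 1])
  expect_false(fit$t1$mask[2, 1, 1])       # all-zero voxel -> invalid
  expect_true(is.na(fit$t1$values[2, 1, 1]))
  # validity mask is a subset of the input mask
  fit2 <- fit_t1_vfa(st, tr_ms = p$tr_ms,
                     mask = array(c(FALSE, TRUE), c(2, 1, 1)))
  expect_false(any(fit2$t1$mask & !array(c(FALSE, TRUE), c(2, 1, 1))))
  # a T2 voxel with fewer than 2 positive echoes is invalid
  bad <- array(c(1000, -1, -1), c(1, 1, 1, 3))
  stb <- signal_stack(bad, c(10, 50, 90), "echo_time_ms")
  fb <- fit_t2(stb, mask = array(TRUE, c(1, 1, 1)))
  expect_false(fb$t2$mask[1, 1, 1])
  expect_error(fit_t1_vfa(signal_stack(array(1, c(1, 1, 1, 1)), 10,
                                       "flip_angle_deg"), tr_ms = 15),
               "2 flip angles")
})

test_that("linearized and refined VFA agree on mildly noisy data; refined matches the grid oracle", {
  p <- acq_protocol()
  dims <- c(10, 10, 10)  # 1000 voxels
  t1 <- array(1000, dims); m0 <- array(1000, dims)
  peak <- max(simulate_vfa_series(t1, m0, p)$volumes)
  st <- simulate_vfa_series(t1, m0, p, noise_sd = 0.005 * peak, seed = 1,
                            noise_model = "gaussian")
  flin <- fit_t1_vfa(st)
  fref <- fit_t1_vfa(st, refine = TRUE)
  rel <- abs(fref$t1$values / flin$t1$values - 1)
  expect_lt(stats::median(rel, na.rm = TRUE), 0.01)
  # refined estimates match an independent grid + polish oracle to 0.1%
  S <- matrix(st$volumes, prod(dims), 9)
  pick <- seq(1, 1000, by = 40)  # 25 voxels, oracle is expensive
  for (j in pick) {
    expect_equal(fref$t1$values[j],
                 oracle_t1(S[j, ], p$flip_angles_deg, p$tr_ms),
                 tolerance = 1e-3)
  }
})

test_that("Rician noise at SNR 50 leaves median T1/T2 bias under 2%", {
  p <- acq_protocol()
  dims <- c(16, 16, 5)  # 1280 voxels
  t1 <- array(1000, dims); m0 <- array(1000, dims)
  peak <- max(simulate_vfa_series(t1, m0, p)$volumes)
  st <- simulate_vfa_series(t1, m0, p, noise_sd = peak / 50, seed = 42)
  fit <- fit_t1_vfa(st, refine = TRUE)
  expect_lt(abs(stats::median(fit$t1$values / 1000 - 1, na.rm = TRUE)), 0.02)
  t2 <- array(100, dims)
  st2 <- simulate_multiecho_series(t2, m0, p, noise_sd = 1000 / 50,
                                   seed = 43)
  f2 <- fit_t2(st2)
  expect_lt(abs(stats::median(f2$t2$values / 100 - 1, na.rm = TRUE)), 0.02)
})
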