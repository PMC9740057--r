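test_that("positive rate is exact by construction across counts and fractions", {
  round_half_up <- function(x) floor(x + 0.5)
  cases <- expand.grid(n = c(10, 137, 1000),
                       f = c(0, 0.122, 0.323, 0.427, 0.543, 1))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; f <- cases$f[i]
    fld <- simulate_histology_field(n, f, necrosis_fraction = 0.1,
                                    seed = 100 + i)
    expect_equal(as.numeric(positive_rate(fld)),
                 100 * round_half_up(n * f) / n, tolerance = 1e-12)
  }
  # a large field accommodates 10^4 nuclei with the same exactness
  big <- simulate_histology_field(10000, 0.543, necrosis_fraction = 0,
                                  field_px = c(1024, 1024), seed = 17)
  expect_equal(as.numeric(positive_rate(big)), 54.3, tolerance = 1e-12)
})

test_that("pooled three-field rates are exact and bounded by per-field rates", {
  flds <- simulate_histology_fields(1000, 0.323, seed = 5)
  r <- positive_rate(flds, marker = "Ki67")
  expect_equal(as.numeric(r), 32.3, tolerance = 1e-12)
  per <- attr(r, "per_field")
  expect_length(per, 3)
  expect_true(min(per) <= as.numeric(r) && as.numeric(r) <= max(per))
  # enumeration oracle: non-touching radius-2 discs are 13 px each
  cls <- flds[[1]]$classes
  expect_equal(sum(cls == HISTO_CLASSES[["positive_nucleus"]]) / 13 /
                 (sum(cls %in% c(1, 2)) / 13) * 100,
               attr(r, "per_field")[1], tolerance = 1e-12)
  expect_equal(as.numeric(positive_rate(
    simulate_histology_field(500, 0, seed = 2))), 0)
})

test_that("necrosis fraction is exact for the printed presets and symmetric cases", {
  # 13 * 690 viable px is divisible by the reduced denominator of 0.862,
  # so the painted fraction is exactly the printed percentage
  f1 <- simulate_histology_field(690, 0.122, 0.862, seed = 3)
  expect_equal(necrosis_fraction(f1), 86.2, tolerance = 1e-12)
  f2 <- simulate_histology_field(817, 0.323, 0.183, seed = 4)
  expect_equal(necrosis_fraction(f2), 18.3, tolerance = 1e-12)
  # saturation: with no viable cells every tissue pixel is necrotic
  f3 <- simulate_histology_field(0, 0, 1, seed = 5)
  expect_equal(necrosis_fraction(f3), 100)
  # checkerboard half necrosis / half nuclei -> 50% exactly
  chk <- matrix(HISTO_CLASSES[["necrosis"]], 8, 8)
  chk[(row(chk) + col(chk)) %% 2 == 0] <- HISTO_CLASSES[["viable_nucleus"]]
  expect_equal(necrosis_fraction(histology_field(chk, 1)), 50)
  # invariance under rotation and flips
  cls <- f2$classes
  for (tr in list(t(cls), cls[nrow(cls):1, ], cls[, ncol(cls):1])) {
    expect_equal(necrosis_fraction(histology_field(tr, 0.5)),
                 necrosis_fraction(f2))
  }
  expect_error(necrosis_fraction(histology_field(
    matrix(HISTO_CLASSES[["background"]], 4, 4), 1)), "no tissue")
})

test_that("vessel areas follow pixel count times squared pixel size", {
  m <- matrix(0L, 32, 32)
  m[5:14, 5:14] <- HISTO_CLASSES[["vessel"]]           # 100 px
  f <- histology_field(m, pixel_size_um = 1)
  va <- vessel_mean_area(f)
  expect_equal(va$mean_area_um2, 100)
  expect_equal(va$n_vessels, 1L)
  m[20:29, 1:30] <- HISTO_CLASSES[["vessel"]]          # 300 px, separate
  va2 <- vessel_mean_area(histology_field(m, pixel_size_um = 0.5))
  expect_equal(sort(va2$areas_um2), c(25, 75))         # (100, 300) * 0.25
  expect_equal(va2$mean_area_um2, 50)
  # zero vessels: missing mean, not zero
  va0 <- vessel_mean_area(histology_field(matrix(
    HISTO_CLASSES[["necrosis"]], 4, 4), 1))
  expect_identical(va0$n_vessels, 0L)
  expect_true(is.na(va0$mean_area_um2))
  # random multi-vessel field matches component enumeration
  fr <- simulate_histology_field(50, 0.5, 0.1, seed = 8,
                                 vessel_spec = c(100, 200, 300))
  var <- vessel_mean_area(fr)
  expect_equal(var$n_vessels, 3L)
  expect_equal(sum(var$areas_um2),
               sum(fr$classes == HISTO_CLASSES[["vessel"]]) *
                 fr$pixel_size_um^2)
})

test_that("field simulation is deterministic under a seed and validates inputs", {
  a <- simulate_histology_field(200, 0.25, 0.3, seed = 7)
  b <- simulate_histology_field(200, 0.25, 0.3, seed = 7)
  expect_identical(a$classes, b$classes)
  c <- simulate_histology_field(200, 0.25, 0.3, seed = 8)
  expect_false(identical(a$classes, c$classes))
  expect_error(simulate_histology_field(10, 1.2, 0.1), "positive_fraction")
  expect_error(simulate_histology_field(10, 0.5, -0.1), "necrosis_fraction")
  expect_error(simulate_histology_field(10, 0.5, 1), "incompatible")
  expect_error(simulate_histology_field(4000, 0.5, 0.1,
                                        field_px = c(64, 64)), "too small")
})

test_that("histology PNG + sidecar round trip preserves the field", {
  f <- simulate_histology_field(100, 0.4, 0.2, seed = 12)
  path <- withr::local_tempfile(fileext = ".png")
  write_histology_field(f, path)
  back <- read_histology_field(path)
  expect_identical(back$classes, f$classes)
  expect_equal(back$pixel_size_um, f$pixel_size_um)
})
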