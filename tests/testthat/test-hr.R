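# High-resolution adaptive half-maximum measurement.

two_plate_profile <- function(x1 = 0.5, x2 = 3.5, thickness = 1.5,
                              sigma = 0.04, step = 0.082, noise_sd = 0,
                              y_js = 35) {
  t <- seq(-4, 8, by = step)
  m <- list(x0 = x1 - thickness, x1 = x1, x2 = x2, x3 = x2 + thickness,
            y0 = 150, y_peak = 1500, y_js = y_js, y3 = 150, sigma = sigma)
  v <- model_profile(m, t)
  if (noise_sd > 0) v <- v + rnorm(length(t), sd = noise_sd)
  profile_from_values(t, v)
}

test_that("half-maximum crossings locate isolated blurred edges exactly", {
  p <- two_plate_profile()
  m <- measure_half_max(p)
  expect_equal(m$status, "ok")
  expect_lt(abs(m$femoral_edge - 0.5), 0.005)
  expect_lt(abs(m$acetabular_edge - 3.5), 0.005)
  expect_lt(abs(m$jsw - 3.0), 0.01)
})

test_that("gap recovery is exact for plates much thicker than the blur", {
  for (g in c(1.0, 2.0, 3.0)) {
    p <- two_plate_profile(x1 = 0.3, x2 = 0.3 + g, thickness = 1.2,
                           sigma = 0.15)
    m <- measure_half_max(p)
    expect_lt(abs(m$jsw - g), 0.01)
  }
})

test_that("noise leaves the mean half-maximum width unbiased", {
  set.seed(77)
  errs <- replicate(100, {
    p <- two_plate_profile(noise_sd = 50)
    measure_half_max(p)$jsw - 3.0
  })
  expect_lt(abs(mean(errs, na.rm = TRUE)), 0.02)
})

test_that("a single plate yields no second peak", {
  t <- seq(-4, 8, by = 0.082)
  m <- list(x0 = -1, x1 = 0.5, x2 = 50, x3 = 51, y0 = 150, y_peak = 1500,
            y_js = 35, y3 = 35, sigma = 0.04)
  p <- profile_from_values(t, model_profile(m, t))
  expect_equal(measure_half_max(p)$status, "no_second_peak")
  flat <- profile_from_values(t, rep(35, length(t)))
  expect_equal(measure_half_max(flat)$status, "failed")
})

test_that("half-maximum bias grows as the blur approaches the structures", {
  # thin plates (0.6 mm): increasing sigma degrades the measurement
  errs <- vapply(c(0.05, 0.15, 0.3), function(s) {
    p <- two_plate_profile(x1 = 0.5, x2 = 2.0, thickness = 0.6, sigma = s)
    m <- measure_half_max(p)
    if (m$status != "ok") Inf else abs(m$jsw - 1.5)
  }, numeric(1))
  expect_true(all(diff(errs) > -1e-9))
  expect_lt(errs[1], 0.01)
})

test_that("coarse profiles are refused", {
  t <- seq(-4, 8, by = 0.5)
  p <- profile_from_values(t, rep(35, length(t)))
  expect_error(measure_half_max(p), "coarse")
})

test_that("outlier filtering removes exactly the contaminated vertices", {
  patch <- retriangulate(hemisphere_patch(), 400)
  nv <- nrow(patch$mesh$vertices)
  map <- jsmap:::new_jsw_map(patch, jsw = rep(3, nv),
                             fit_error = rep(NA_real_, nv),
                             femoral_offset = rep(0.2, nv),
                             flags = rep("ok", nv), method = "hr_half_max")
  clean <- filter_hr_outliers(map)
  expect_equal(attr(clean, "removed_frac"), 0)
  expect_equal(clean$jsw, map$jsw)

  set.seed(5)
  bad <- sample(nv, round(0.05 * nv))
  map$femoral_offset[bad] <- 4
  filt <- filter_hr_outliers(map)
  expect_true(all(is.na(filt$jsw[bad])))
  expect_true(all(is.finite(filt$jsw[-bad])))
  expect_equal(attr(filt, "removed_frac"), length(bad) / nv)

  # idempotence
  again <- filter_hr_outliers(filt)
  expect_equal(again$jsw, filt$jsw)
  expect_equal(again$flags, filt$flags)
})
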