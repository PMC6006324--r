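test_that("the blurred model has the analytic values at key points", {
  # vanishing blur: joint tissue density in the middle of a wide gap
  m <- double_peak_model(-6, -4, 4, 6, y0 = 300, y_peak = 1500, y_js = 35,
                         y3 = 150, sigma = 1e-9)
  expect_equal(model_profile(m, 0), 35)
  # at an isolated edge a blurred step passes through its midpoint
  m2 <- double_peak_model(-9, -6, 0, 6, y0 = 300, y_peak = 1500, y_js = 35,
                          y3 = 150, sigma = 0.5)
  expect_equal(model_profile(m2, 0), (1500 + 35) / 2)
  expect_error(double_peak_model(0, -1, 2, 3, 300, 1500, 35, 150, 0.8))
})

test_that("closed form matches brute-force numerical convolution", {
  sigma <- 0.8
  edges <- c(-3, -1.5, 1.5, 3)
  lv <- c(300, 1500, 35, 1500, 150)
  dt <- 0.005
  tg <- seq(-20, 20, by = dt)
  # symmetric value at samples landing exactly on an edge, so the discrete
  # sequence represents steps centred on the stated positions
  step_prof <- (lv[1 + findInterval(tg - 1e-9, edges)] +
                lv[1 + findInterval(tg + 1e-9, edges)]) / 2
  kern <- dnorm(seq(-6 * sigma, 6 * sigma, by = dt), sd = sigma)
  kern <- kern / sum(kern)
  conv <- stats::filter(step_prof, kern, sides = 2)
  m <- double_peak_model(edges[1], edges[2], edges[3], edges[4], y0 = lv[1],
                         y_peak = lv[2], y_js = lv[3], y3 = lv[5],
                         sigma = sigma)
  sel <- which(!is.na(conv) & abs(tg) <= 8)
  expect_lt(max(abs(model_profile(m, tg[sel]) - conv[sel])), 0.1)
})

test_that("noisy profiles are fitted without bias and with sub-voxel spread", {
  m <- double_peak_model(-2.5, -1.0, 2.0, 3.5, y0 = 300, y_peak = 1500,
                         y_js = 35, y3 = 150, sigma = 0.8)
  p <- analytic_profile(m)
  set.seed(42)
  errs <- replicate(100, {
    pn <- p
    pn$values <- p$values + rnorm(length(p$t), sd = 20)
    fit_double_peak(pn, y_peak = 1500)$jsw - 3.0
  })
  expect_lt(abs(mean(errs, na.rm = TRUE)), 0.05)
  expect_lt(sd(errs, na.rm = TRUE), 0.15)
})

test_that("a single cortex with nothing beyond reports no opposing bone", {
  m <- list(x0 = -2.5, x1 = -1.0, x2 = 40, x3 = 41.5, y0 = 300,
            y_peak = 1500, y_js = 35, y3 = 35, sigma = 0.8)
  f <- fit_double_peak(analytic_profile(m), y_peak = 1500)
  expect_equal(f$status, "no_opposing_bone")
  expect_true(is.na(f$jsw))
})

test_that("measured width is monotone in the true gap", {
  jsw <- vapply(c(1.6, 2.2, 3.0, 4.0), function(g) {
    m <- double_peak_model(-2.5, -1.0, -1.0 + g, 0.5 + g, y0 = 300,
                           y_peak = 1500, y_js = 35, y3 = 150, sigma = 0.9)
    fit_double_peak(analytic_profile(m), y_peak = 1500)$jsw
  }, numeric(1))
  expect_true(all(diff(jsw) > 0))
})

test_that("peak cortical density is recovered from a shell phantom", {
  mesh <- shell_mesh()
  cfg <- jsm_config(peak_sample = 400, seed = 3L)
  blurred <- shell_phantom(0.8)
  est <- estimate_peak_density(blurred$volume, mesh, cfg)
  expect_lt(abs(est - 1400) / 1400, 0.05)
  # near-unblurred data: linear interpolation avoids cubic overshoot at the
  # (almost) discontinuous edges
  cfg_lin <- jsm_config(peak_sample = 400, seed = 3L, interp = "linear")
  sharp <- shell_phantom(0.05)
  est2 <- estimate_peak_density(sharp$volume, mesh, cfg_lin)
  expect_lt(abs(est2 - 1400) / 1400, 0.01)
})

test_that("peak estimation fails on a cortex-free volume", {
  mesh <- shell_mesh()
  flat <- image_volume(array(100, dim(shell_phantom(0.8)$volume$data)),
                       affine = shell_phantom(0.8)$volume$affine)
  expect_error(estimate_peak_density(flat, mesh, jsm_config(peak_sample = 300)),
               "failed")
})
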