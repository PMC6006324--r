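test_that("phantom generation is deterministic given spec and seed", {
  spec <- phantom_spec("plates", gap = 2, spacing = c(0.5, 0.5, 0.5),
                       plate_extent = 6, margin = 3, seed = 9L)
  a <- generate_volume(spec)
  b <- generate_volume(spec)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_identical(a$boundary, b$boundary)
})

test_that("a gap voxel holds joint tissue density without blur or noise", {
  spec <- phantom_spec("plates", gap = 3, psf = c(0, 0, 0),
                       psf_is_fwhm = FALSE, noise_sd = 0,
                       spacing = c(0.5, 0.5, 0.5), plate_extent = 6,
                       margin = 3)
  ph <- generate_volume(spec)
  centre <- world_to_voxel(ph$volume, matrix(c(0, 0, 1.5), 1))
  val <- ph$volume$data[round(centre[1]) + 1, round(centre[2]) + 1,
                        round(centre[3]) + 1]
  expect_equal(val, 35)
})

test_that("a blurred plate profile matches the closed-form model", {
  # fine z-supersampling so the realised edges sit exactly at the nominal
  # positions; the oracle sigma folds in the analytic voxel-averaging term
  spec <- phantom_spec("plates", gap = 3, psf = rep(0.6, 3),
                       psf_is_fwhm = FALSE, noise_sd = 0,
                       spacing = c(0.4, 0.4, 0.4), plate_extent = 6,
                       margin = 4, supersample = c(1, 1, 201))
  ph <- generate_volume(spec)
  # probe at voxel centres along z so no interpolation enters the oracle
  p <- sample_profile(ph$volume, c(0, 0, 0), c(0, 0, 1), -3.7, 6.7, 0.4)
  d <- spec$densities
  sigma_eff <- sqrt(0.6^2 + 0.4^2 / 12)
  m <- list(x0 = -spec$cortex_thickness, x1 = 0, x2 = 3,
            x3 = 3 + spec$cortex_thickness, y0 = d[["interior"]],
            y_peak = d[["cortex"]], y_js = d[["joint_tissue"]],
            y3 = d[["far"]], sigma = sigma_eff)
  expect_lt(sqrt(mean((p$values - model_profile(m, p$t))^2)), 1)
})

test_that("the realised edge blur equals the specified PSF sigma", {
  spec <- phantom_spec("plates", gap = 6, psf = rep(0.8, 3),
                       psf_is_fwhm = FALSE, noise_sd = 0,
                       spacing = c(0.25, 0.25, 0.25), plate_extent = 4,
                       margin = 3, cortex_thickness = 6,
                       supersample = c(1, 1, 201))
  ph <- generate_volume(spec)
  # probe at voxel centres (z = 0.125 + 0.25 k) to keep interpolation out
  p <- sample_profile(ph$volume, c(0, 0, 0), c(0, 0, 1), -1.875, 1.875, 0.25)
  # fit an erf edge (cortex -> joint tissue at z = 0) for its sigma; the
  # expected spread folds in the analytic voxel-averaging term
  d <- spec$densities
  sigma_eff <- sqrt(0.8^2 + 0.25^2 / 12)
  fit <- minpack.lm::nls.lm(
    par = c(edge = 0.1, sigma = 0.5),
    fn = function(q) d[["cortex"]] + (d[["joint_tissue"]] - d[["cortex"]]) *
      pnorm((p$t - q[1]) / q[2]) - p$values)
  expect_lt(abs(fit$par[["sigma"]] - sigma_eff) / sigma_eff, 0.02)
  expect_lt(abs(fit$par[["edge"]]), 0.05)
})

test_that("ball-and-socket ground truth follows the gap function", {
  spec <- phantom_spec("ball_socket", gap = 3)
  patch <- clinical_phantom()$patch
  gt_const <- ground_truth_jsw(spec, patch)
  expect_true(all(gt_const[is.finite(gt_const)] == 3))

  spec2 <- phantom_spec("ball_socket",
                        gap_function = function(th, ph) 2.5 + 1.0 * cos(th),
                        cap_angle = 90)
  pole <- triangle_mesh(rbind(c(0, 0, 20), c(0.5, 0, 19.99), c(0, 0.5, 19.99)),
                        rbind(c(1, 2, 3)))
  expect_equal(ground_truth_jsw(spec2, pole)[1], 3.5)
  eq <- triangle_mesh(rbind(c(20, 0, 0), c(19.99, 0.5, 0), c(19.99, 0, 0.5)),
                      rbind(c(1, 2, 3)))
  expect_equal(ground_truth_jsw(spec2, eq)[1], 2.5)

  off <- triangle_mesh(rbind(c(0, 0, 25), c(1, 0, 25), c(0, 1, 25)),
                       rbind(c(1, 2, 3)))
  expect_error(ground_truth_jsw(spec, off), "off the femoral surface")
})

test_that("ground truth agrees with dense ray casting through the geometry", {
  spec <- clinical_spec()
  # cast fine radial rays through the continuous geometry and read off the
  # joint tissue extent
  set.seed(31)
  th <- runif(20, 0.05, spec$boundary_angle * pi / 180)
  phi <- runif(20, 0, 2 * pi)
  for (k in seq_along(th)) {
    dir <- c(sin(th[k]) * cos(phi[k]), sin(th[k]) * sin(phi[k]), cos(th[k]))
    tt <- seq(0, 8, by = 0.002)
    r <- 20 + tt
    dens <- jsmap:::phantom_density(spec, dir[1] * r, dir[2] * r, dir[3] * r)
    gap_len <- 0.002 * sum(dens == 35)
    truth <- clinical_gap_fun(th[k], phi[k])
    expect_equal(gap_len, truth, tolerance = 0.01)
  }
})

test_that("operator simulation produces controlled boundary jitter", {
  spec <- phantom_spec("ball_socket", seed = 12L)
  same <- simulate_two_operators(spec, 0)
  expect_identical(same$op1, same$op2)
  ops <- simulate_two_operators(spec, 2)
  d <- sqrt(rowSums((ops$op1 - ops$op2)^2))
  expect_gte(mean(d), 1)
  expect_lte(mean(d), 3)
  # loops stay on the femoral sphere
  expect_lt(max(abs(sqrt(rowSums(ops$op2^2)) - 20)), 1e-6)
})

test_that("negative gaps are rejected", {
  expect_error(phantom_spec("ball_socket",
                            gap_function = function(th, ph) cos(th) - 0.51),
               "non-negative")
})
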