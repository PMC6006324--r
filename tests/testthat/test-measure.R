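# Constructed map helpers ----------------------------------------------------

uniform_map <- function(jsw = 3, err = 10) {
  patch <- retriangulate(hemisphere_patch(), 400)
  nv <- nrow(patch$mesh$vertices)
  jsmap:::new_jsw_map(patch, jsw = rep(jsw, nv), fit_error = rep(err, nv),
                      femoral_offset = rep(0, nv),
                      flags = rep("ok", nv))
}

test_that("patch measurement succeeds across a clinical-regime phantom", {
  cp <- clinical_phantom()
  map <- clinical_map()
  expect_gte(mean(map$flags == "ok"), 0.95)
  ok <- map$flags == "ok" & is.finite(cp$gt)
  expect_lt(abs(median(map$jsw[ok] - cp$gt[ok])), 0.15)
  td <- tidy(map)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(cp$patch$mesh$vertices))
  expect_equal(glance(map)$n_ok, sum(map$flags == "ok"))
})

test_that("the peak density constraint is estimated near the true cortex", {
  cp <- clinical_phantom()
  expect_lt(abs(cp$y_peak - 1400) / 1400, 0.05)
})

test_that("a patch outside the volume is a pipeline error", {
  cp <- clinical_phantom()
  p2 <- cp$patch
  p2$mesh$vertices <- p2$mesh$vertices + 500
  expect_error(measure_patch(p2, cp$ph$volume, y_peak = cp$y_peak),
               "outside")
})

test_that("steep-gradient outliers are flattened, smooth maps untouched", {
  map <- uniform_map()
  adj <- jsmap:::vertex_adjacency(map$patch$mesh)
  interior <- which(interior_vertices(map$patch, 2))
  spike <- interior[1]
  map$jsw[spike] <- 8
  map$femoral_offset[spike] <- 3
  out <- remove_outliers(map)
  expect_lt(abs(out$jsw[spike] - 3), 0.2)
  expect_equal(out$flags[spike], "refilled")

  # two adjacent spikes are both caught (ring median, not mean)
  map2 <- uniform_map()
  s1 <- interior[5]
  s2 <- intersect(adj[[s1]], interior)[1]
  map2$femoral_offset[c(s1, s2)] <- 3
  map2$jsw[c(s1, s2)] <- 8
  out2 <- remove_outliers(map2)
  expect_true(all(abs(out2$jsw[c(s1, s2)] - 3) < 0.2))

  # smooth input: (almost) nothing altered
  clean <- remove_outliers(uniform_map())
  expect_lte(attr(clean, "n_removed"), 0.01 * sum(clean$flags != ""))
})

test_that("outlier removal never alters more than the configured fraction", {
  map <- uniform_map()
  set.seed(9)
  cand <- which(interior_vertices(map$patch, 2))
  bad <- sample(cand, min(80, length(cand)))
  map$femoral_offset[bad] <- map$femoral_offset[bad] + 5
  out <- remove_outliers(map)
  expect_lte(attr(out, "n_removed"), ceiling(0.1 * sum(map$flags == "ok")))
})

test_that("error-based smoothing is anchored and noise-reducing", {
  map <- uniform_map()
  sm <- smooth_map(map)
  expect_lt(max(abs(sm$jsw - 3)), 1e-9)  # uniform maps are fixed points

  set.seed(21)
  noisy <- uniform_map()
  noise <- rnorm(length(noisy$jsw), sd = 0.2)
  noisy$jsw <- noisy$jsw + noise
  sm2 <- smooth_map(noisy)
  expect_lt(sqrt(mean((sm2$jsw - 3)^2)), sqrt(mean(noise^2)))

  # a high-error vertex moves most of the way to its neighbours
  m3 <- uniform_map(err = 5)
  i <- which(interior_vertices(m3$patch, 2))[3]
  m3$jsw[i] <- 5
  m3$fit_error[i] <- 500
  sm3 <- smooth_map(m3)
  expect_gte((5 - sm3$jsw[i]) / (5 - 3), 0.5)
})

test_that("joint surfaces enclose the measured joint space", {
  map <- uniform_map(jsw = 3)
  surf <- build_joint_surfaces(map)
  d <- sqrt(rowSums((surf$acetabular$vertices - surf$femoral$vertices)^2))
  expect_equal(mean(d), 3, tolerance = 0.1)
  # spherical geometry: acetabular radius ~ femoral radius + gap
  rf <- sqrt(rowSums(surf$femoral$vertices^2))
  ra <- sqrt(rowSums(surf$acetabular$vertices^2))
  expect_equal(mean(ra - rf), 3, tolerance = 0.05)

  zero <- uniform_map(jsw = 0)
  s0 <- build_joint_surfaces(zero)
  expect_equal(s0$femoral$vertices, s0$acetabular$vertices)

  few <- uniform_map()
  few$flags[seq_len(round(0.3 * length(few$flags)))] <- "fit_failed"
  expect_error(build_joint_surfaces(few), "80")
})
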