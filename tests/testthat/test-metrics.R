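test_that("95% trimming keeps exactly the central mass", {
  set.seed(123)
  u <- runif(1000)
  tr <- trim_95(u)
  expect_equal(sum(is.finite(tr)), 950)

  same <- rep(2.5, 50)
  expect_equal(sum(is.finite(trim_95(same))), 50)

  v <- as.numeric(1:100)
  kept <- sort(v[is.finite(trim_95(v))])
  expect_equal(kept, as.numeric(3:98))

  # idempotence
  expect_equal(trim_95(trim_95(u)), trim_95(u))
  expect_error(trim_95(1:10), "40")
})

test_that("accuracy and precision follow the worked examples", {
  a <- c(3.1, 2.9, 3.3, 2.7)
  expect_equal(accuracy_precision(a, a), list(bias = 0, precision = 0, n = 4))
  res <- accuracy_precision(a + 0.5, a)
  expect_equal(res$bias, 0.5)
  expect_equal(res$precision, 0)
  b <- a - c(0.1, -0.1, 0.3, -0.3)
  res2 <- accuracy_precision(a, b)
  expect_equal(res2$bias, 0)
  expect_equal(res2$precision, 0.2582, tolerance = 1e-4)
  # antisymmetry of the bias, symmetry of the precision
  res3 <- accuracy_precision(b, a)
  expect_equal(res3$bias, -res2$bias)
  expect_equal(res3$precision, res2$precision)
  expect_error(accuracy_precision(c(NA, NA), c(1, 2)), "matched")
})

test_that("Bland-Altman limits match hand computation", {
  a <- c(3.1, 2.9, 3.3, 2.7)
  ba0 <- bland_altman(a, a)
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa, 0)
  b <- a - c(0.1, -0.1, 0.3, -0.3)
  ba <- bland_altman(a, b)
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, 1.96 * 0.2582, tolerance = 1e-3)
  swapped <- bland_altman(b, a)
  expect_equal(swapped$bias, -ba$bias)
  expect_equal(swapped$loa, ba$loa)
  expect_error(bland_altman(1, 1), "2 pairs")
  expect_s3_class(autoplot(ba), "ggplot")
})

test_that("RMSCV matches hand computation and is scale invariant", {
  expect_equal(rmscv(cbind(c(2, 3), c(2, 3))), 0)
  expect_equal(rmscv(rbind(c(2.0, 2.2))), 6.734, tolerance = 1e-3)
  three <- rbind(c(2.0, 2.2), c(3.0, 3.0), c(4.0, 3.6))
  expect_equal(rmscv(three), 5.795, tolerance = 1e-3)
  expect_equal(rmscv(three * 7), rmscv(three))
  expect_error(rmscv(rbind(c(1, -1))), "undefined")
})

test_that("per-vertex aggregation reproduces the global statistics", {
  set.seed(8)
  nv <- 200
  ns <- 5
  A <- replicate(ns, 3 + rnorm(nv, sd = 0.2), simplify = FALSE)
  B <- lapply(A, function(x) x + rnorm(nv, sd = 0.1))
  pv <- per_vertex_maps(A, B)
  expect_equal(nrow(pv), nv)
  expect_true(all(pv$n == ns))
  expect_true(all(pv$rmscv >= 0, na.rm = TRUE))
  # identical collections: zero bias field
  pv0 <- per_vertex_maps(A, A)
  expect_true(all(pv0$bias == 0))
  # one subject offset by +0.5 among five: per-vertex bias +0.1
  B2 <- A
  B2[[2]] <- A[[2]] - 0.5
  pv2 <- per_vertex_maps(A, B2)
  expect_equal(pv2$bias, rep(0.1, nv))
  # the count-weighted mean of per-vertex biases equals the global bias
  g <- accuracy_precision(unlist(A), unlist(B))
  expect_equal(sum(pv$bias * pv$n) / sum(pv$n), g$bias)
  # vertices with too few subjects are masked
  A3 <- lapply(A, function(x) { x[1:10] <- NA; x })
  pv3 <- per_vertex_maps(A3, B, min_subjects = 3)
  expect_true(all(is.na(pv3$bias[1:10])))
})

test_that("the agreement report bundles the validation metrics", {
  set.seed(13)
  a <- 3 + rnorm(500, sd = 0.3)
  b <- a - 0.13 + rnorm(500, sd = 0.1)
  rep <- agreement_report(a, b, trim = TRUE)
  expect_equal(rep$bias, 0.13, tolerance = 0.05)
  expect_equal(rep$loa, 1.96 * rep$precision)
  expect_s3_class(glance(rep), "tbl_df")
})
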