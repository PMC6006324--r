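small_ball_volume <- function() fixture("small_ball_volume", function() {
  spec <- phantom_spec("ball_socket", femoral_radius = 10,
                       spacing = c(1, 1, 1), noise_sd = 0, margin = 4,
                       cap_angle = 60, gap = 3)
  generate_volume(spec)$volume
})

test_that("self-registration returns the identity", {
  v <- small_ball_volume()
  tr <- register_volumes_mi(v, v, levels = 1, max_samples = 8000)
  expect_lt(max(abs(tr$translation)), 0.05)
  expect_lt(jsmap:::rotation_angle_deg(tr$rotation), 0.1)
  expect_gte(attr(tr, "mi_final"), attr(tr, "mi_initial") - 1e-9)
})

test_that("a known translation is recovered", {
  v <- small_ball_volume()
  mv <- v
  mv$affine[1:3, 4] <- mv$affine[1:3, 4] + c(2, -1, 3)
  tr <- register_volumes_mi(v, mv, levels = 2, max_samples = 8000)
  expect_lt(max(abs(tr$translation - c(2, -1, 3))), 0.2)
  expect_lt(abs(tr$scale - 1), 0.02)
})

test_that("constant volumes trigger the degenerate-MI warning", {
  flat <- image_volume(array(7, c(16, 16, 16)), spacing = c(1, 1, 1))
  expect_warning(tr <- register_volumes_mi(flat, flat), "degenerate")
  expect_equal(tr$translation, c(0, 0, 0))
})

test_that("registering A to B and B to A composes to near-identity", {
  v <- small_ball_volume()
  mv <- v
  mv$affine[1:3, 4] <- mv$affine[1:3, 4] + c(1.5, -0.5, 1)
  ab <- register_volumes_mi(v, mv, levels = 2, max_samples = 6000)
  ba <- register_volumes_mi(mv, v, levels = 2, max_samples = 6000)
  pts <- matrix(rnorm(30, sd = 5), 10, 3)
  round_trip <- apply_transform(ba, apply_transform(ab, pts))
  expect_lt(max(abs(round_trip - pts)), 0.3)
})

test_that("surface self-registration is the identity with a null warp", {
  pm <- bumpy_patch_mesh()
  reg <- register_surfaces(pm, pm)
  expect_lt(abs(reg$similarity$scale - 1), 1e-6)
  expect_lt(jsmap:::rotation_angle_deg(reg$similarity$rotation), 0.01)
  disp <- apply_transform(reg, pm$vertices) - pm$vertices
  expect_lt(max(abs(disp)), 0.01)
})

test_that("a known similarity transform is recovered through ICP + TPS", {
  pm <- bumpy_patch_mesh()
  ang <- 10 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  tr_true <- similarity_transform(R, c(5, 2, -3), 1.1)
  tgt <- triangle_mesh(apply_transform(tr_true, pm$vertices), pm$triangles)
  reg <- register_surfaces(pm, tgt)
  expect_lt(abs(reg$similarity$scale - 1.1) / 1.1, 0.01)
  rel <- reg$similarity$rotation %*% t(R)
  expect_lt(jsmap:::rotation_angle_deg(rel), 0.5)
  expect_lt(sqrt(sum((reg$similarity$translation - c(5, 2, -3))^2)), 0.2)
  expect_lte(reg$residual_tps, reg$residual_similarity + 1e-12)
})

test_that("TPS interpolates landmarks exactly at zero regularisation", {
  set.seed(5)
  src <- matrix(rnorm(60), 20, 3)
  dst <- src + matrix(rnorm(60, sd = 0.5), 20, 3)
  tps <- tps_transform(src, dst, lambda = 0)
  expect_lt(max(abs(apply_transform(tps, src) - dst)), 1e-6)
  # bending energy is non-increasing in lambda
  en <- vapply(c(0, 0.01, 0.1, 1), function(l)
    jsmap:::tps_bending_energy(tps_transform(src, dst, lambda = l)),
    numeric(1))
  expect_true(all(diff(en) <= 1e-9))
  flat <- cbind(rnorm(10), rnorm(10), 0)  # coplanar
  expect_error(tps_transform(flat, flat), "degenerate")
})

test_that("value transfer preserves values, constants and ranges", {
  pm <- bumpy_patch_mesh()
  vals <- pm$vertices[, 3] - min(pm$vertices[, 3])
  # identity transfer, no smoothing: values survive the nearest-vertex hop
  out <- transfer_values(vals, pm, NULL, pm, smooth_iterations = 0)
  expect_equal(out, vals)
  # constants are fixed points of the smoothing pass
  cst <- transfer_values(rep(2.5, nrow(pm$vertices)), pm, NULL, pm)
  expect_equal(cst, rep(2.5, nrow(pm$vertices)))
  # a known vertex permutation is undone by nearest-vertex matching
  set.seed(6)
  perm <- sample(nrow(pm$vertices))
  shuffled <- triangle_mesh(pm$vertices[perm, ], matrix(order(perm)[pm$triangles],
                                                        ncol = 3))
  out2 <- transfer_values(vals[perm], shuffled, NULL, pm,
                          smooth_iterations = 0)
  expect_equal(out2, vals)
  # smoothing is a convex combination: no new extrema
  sm <- transfer_values(vals, pm, NULL, pm, smooth_iterations = 2)
  expect_gte(min(sm), min(vals) - 1e-12)
  expect_lte(max(sm), max(vals) + 1e-12)
})

test_that("averaging surfaces is idempotent and finds the midpoint", {
  pm <- bumpy_patch_mesh()
  avg <- build_average_surface(list(pm, pm, pm), target_vertex_count = 700,
                               iterations = 1)
  d <- jsmap:::point_mesh_dist_cpp(avg$mesh$vertices, pm$vertices,
                                   pm$triangles)
  expect_lt(mean(d), 0.01)
  expect_gte(nrow(avg$mesh$vertices), 630)
  expect_lte(nrow(avg$mesh$vertices), 770)

  nrm <- vertex_normals(pm)
  m1 <- triangle_mesh(pm$vertices + 1.0 * nrm, pm$triangles)
  m2 <- triangle_mesh(pm$vertices - 1.0 * nrm, pm$triangles)
  avg2 <- build_average_surface(list(m1, m2), target_vertex_count = 700,
                                iterations = 2)
  d2 <- jsmap:::point_mesh_dist_cpp(avg2$mesh$vertices, pm$vertices,
                                    pm$triangles)
  expect_lt(mean(d2), 0.05)
  expect_error(build_average_surface(list(pm)), "at least 2")
})
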