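test_that("mesh extraction recovers a sphere's area and outward normals", {
  mesh <- sphere_mesh()
  expect_lt(abs(mesh_area(mesh) - 4 * pi * 100) / (4 * pi * 100), 0.02)
  expect_true(all(rowSums(mesh$normals * mesh$vertices) > 0))
  r <- sqrt(rowSums(mesh$vertices^2))
  expect_lt(max(abs(r - 10)), 0.5)
})

test_that("an empty mask is rejected", {
  empty <- image_volume(array(0, c(10, 10, 10)), spacing = c(1, 1, 1))
  expect_error(mesh_from_mask(empty), "empty")
})

test_that("opposing-bone projection finds a plate within reach only", {
  # 35 HU background with a 1500 HU plate spanning z in [3, 4.5] mm
  n <- c(40, 40, 40)
  sp <- c(0.5, 0.5, 0.5)
  org <- c(-10, -10, -5)
  zs <- org[3] + sp[3] * (0:(n[3] - 1))
  vol1 <- array(35, n)
  vol1[, , zs > 3 & zs < 4.5] <- 1500
  v1 <- image_volume(vol1, spacing = sp, origin = org)
  # single-vertex "mesh" at the origin looking up +z
  m <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                     rbind(c(1, 2, 3)))
  m$normals <- matrix(rep(c(0, 0, 1), each = 3), ncol = 3)
  f <- project_opposing_bone(m, v1, search_depth = 5)
  expect_equal(f[1], 1500, tolerance = 1)

  v2 <- image_volume(array(35, n), spacing = sp, origin = org)
  expect_equal(project_opposing_bone(m, v2, search_depth = 5)[1], 35,
               tolerance = 1e-6)

  vol3 <- array(35, n)
  vol3[, , zs > 6 & zs < 7.5] <- 1500   # plate beyond the 5 mm search
  v3 <- image_volume(vol3, spacing = sp, origin = org)
  f5 <- project_opposing_bone(m, v3, search_depth = 5, interp = "linear")
  expect_equal(f5[1], 35, tolerance = 1e-6)
  # enlarging the search depth never decreases the projected value
  f8 <- project_opposing_bone(m, v3, search_depth = 8, interp = "linear")
  expect_true(all(f8 >= f5 - 1e-9))
  expect_equal(f8[1], 1500, tolerance = 1)
  expect_error(project_opposing_bone(m, v3, search_depth = -1))
})

test_that("cutting along the equator yields a hemisphere patch", {
  patch <- hemisphere_patch()
  expect_s3_class(patch, "joint_space_patch")
  expect_lt(abs(mesh_area(patch$mesh) - 2 * pi * 100) / (2 * pi * 100), 0.03)
  expect_true(all(patch$mesh$vertices[setdiff(seq_len(nrow(patch$mesh$vertices)),
                                              patch$boundary), 3] > -0.6))
  expect_gt(length(patch$boundary), 30)
})

test_that("patch vertices and complement partition the mesh", {
  mesh <- sphere_mesh()
  phi <- seq(0, 2 * pi, length.out = 73)
  loop <- cbind(10 * cos(phi), 10 * sin(phi), 0)
  north <- cut_patch(mesh, loop, seed = c(0, 0, 10))
  south <- cut_patch(mesh, loop, seed = c(0, 0, -10))
  # recover parent indices by matching coordinates through nearest neighbour
  nn_n <- jsmap:::nn_index_cpp(north$mesh$vertices, mesh$vertices)
  nn_s <- jsmap:::nn_index_cpp(south$mesh$vertices, mesh$vertices)
  expect_equal(max(nn_n$dist), 0)
  expect_equal(max(nn_s$dist), 0)
  ids_n <- nn_n$index
  ids_s <- nn_s$index
  expect_setequal(union(ids_n, ids_s), seq_len(nrow(mesh$vertices)))
  both <- intersect(ids_n, ids_s)
  expect_setequal(both, ids_n[north$boundary])
})

test_that("invalid boundary polylines are rejected", {
  mesh <- sphere_mesh()
  phi <- seq(0, 2 * pi, length.out = 73)
  open_line <- cbind(10 * cos(phi[1:40]), 10 * sin(phi[1:40]), 0)
  expect_error(cut_patch(mesh, open_line, seed = c(0, 0, 10)), "closed")
  # figure-of-eight: crosses itself on the sphere
  s <- seq(0, 2 * pi, length.out = 81)
  fig8 <- cbind(10 * sin(2 * s) * 0.4, 10 * sin(s) * 0.9, 0)
  fig8 <- sweep(fig8, 1, sqrt(rowSums(fig8^2)) / 10 + 1e-9, "/")
  fig8[, 3] <- sqrt(pmax(100 - rowSums(fig8[, 1:2]^2), 0))
  fig8[nrow(fig8), ] <- fig8[1, ]
  expect_error(cut_patch(mesh, fig8, seed = c(0, 0, 10)),
               "self-intersecting")
  far <- cbind(40 * cos(phi), 40 * sin(phi), 0)
  expect_error(cut_patch(mesh, far, seed = c(0, 0, 10)), "snapped")
})

test_that("re-triangulation hits the target count and stays on the surface", {
  patch <- hemisphere_patch()
  small <- retriangulate(patch, 1000)
  expect_gte(nrow(small$mesh$vertices), 900)
  expect_lte(nrow(small$mesh$vertices), 1100)
  big <- retriangulate(small, 4000)
  expect_gte(nrow(big$mesh$vertices), 3600)
  expect_lte(nrow(big$mesh$vertices), 4400)
  # geometric fidelity: within half the mean input edge length
  ed <- jsmap:::mesh_edges(small$mesh)$edges
  elen <- sqrt(rowSums((small$mesh$vertices[ed[, 1], ] -
                        small$mesh$vertices[ed[, 2], ])^2))
  expect_lt(mesh_hausdorff(big$mesh, small$mesh), mean(elen) / 2)
  expect_lt(abs(mesh_area(big$mesh) - 2 * pi * 100) / (2 * pi * 100), 0.03)
  # near-identity retriangulation
  same <- retriangulate(small, nrow(small$mesh$vertices))
  expect_lt(mesh_hausdorff(same$mesh, small$mesh), mean(elen) / 2)
  expect_error(retriangulate(patch, 50), "100")
})

test_that("retriangulated normals track the source surface", {
  patch <- hemisphere_patch()
  big <- retriangulate(retriangulate(patch, 1000), 3000)
  # on a sphere the exact normal is radial
  v <- big$mesh$vertices
  radial <- v / sqrt(rowSums(v^2))
  ang <- acos(pmin(pmax(rowSums(big$mesh$normals * radial), -1), 1)) * 180 / pi
  interior <- !(seq_len(nrow(v)) %in% big$boundary)
  expect_lt(max(ang[interior]), 15)
})
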