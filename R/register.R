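#' Similarity transform (rotation, translation, isotropic scale)
#'
#' Maps points as `scale * rotation %*% x + translation`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 vector (mm).
#' @param scale positive scalar.
#' @export
similarity_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                                 scale = 1) {
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation must be orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det +1)")
  if (scale <= 0) stop("scale must be positive")
  structure(list(rotation = rotation, translation = as.numeric(translation),
                 scale = scale), class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("similarity_transform: scale %.4f, rotation %.2f deg, translation (%s) mm\n",
              x$scale, ang, paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

#' Apply a spatial transform to points
#' @param transform a `similarity_transform`, `tps_transform` or
#'   `surface_registration`.
#' @param pts n x 3 matrix.
#' @return n x 3 matrix of transformed points.
#' @export
apply_transform <- function(transform, pts) UseMethod("apply_transform")

#' @export
apply_transform.similarity_transform <- function(transform, pts) {
  pts <- as.matrix(pts)
  sweep(pts %*% t(transform$rotation) * transform$scale, 2,
        -transform$translation)
}

rotation_angle_deg <- function(R) {
  c <- (sum(diag(R)) - 1) / 2
  acos(pmin(pmax(c, -1), 1)) * 180 / pi
}

euler_to_rotation <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx)
  cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

params_to_similarity <- function(p) {
  similarity_transform(rotation = euler_to_rotation(p[1], p[2], p[3]),
                       translation = p[4:6], scale = exp(p[7]))
}

#' Mutual-information similarity registration of two volumes
#'
#' Finds the similarity transform (rotation, translation, isotropic scale)
#' mapping fixed-volume world coordinates into the moving volume that
#' maximises the mutual information of the joint intensity histogram.  A
#' multiresolution pyramid with Nelder-Mead optimisation at each level is
#' used; the criterion is evaluated on a subsample of informative (above
#' background) fixed voxels.
#'
#' @param fixed,moving [image_volume] objects.
#' @param init initial `similarity_transform` (identity by default).
#' @param bins joint histogram bins per axis (default 64).
#' @param levels pyramid levels (default 3).
#' @param max_samples fixed-voxel subsample size per level.
#' @param seed RNG seed for the subsample.
#' @return A `similarity_transform` with attributes `mi_initial` and
#'   `mi_final` (the final MI is never below the initial one).
#' @export
register_volumes_mi <- function(fixed, moving, init = similarity_transform(),
                                bins = 64, levels = 3, max_samples = 15000,
                                seed = 1L) {
  if (sd(fixed$data) < 1e-12 || sd(moving$data) < 1e-12) {
    warning("degenerate registration: a volume is constant (zero MI gradient)")
    return(init)
  }
  p <- c(rot_params(init$rotation), init$translation, log(init$scale))
  pyr_f <- volume_pyramid(fixed, levels)
  pyr_m <- volume_pyramid(moving, levels)
  set.seed(seed)
  mi0 <- NA_real_
  for (lv in seq(levels, 1)) {
    f <- pyr_f[[lv]]
    m <- pyr_m[[lv]]
    pts_all <- informative_points(f)
    n <- nrow(pts_all)
    pts <- pts_all[sample.int(n, min(n, max_samples)), , drop = FALSE]
    fvals <- sample_volume_cpp(as.numeric(f$data), dim(f$data),
                               world_to_voxel(f, pts), 1L)$values
    neg_mi <- function(par) {
      tr <- params_to_similarity(par)
      q <- world_to_voxel(m, apply_transform(tr, pts))
      res <- sample_volume_cpp(as.numeric(m$data), dim(m$data), q, 1L)
      keep <- !res$oob
      if (sum(keep) < 100) return(0)
      -mutual_information(fvals[keep], res$values[keep], bins)
    }
    scale_t <- max(f$spacing)
    # coarse capture-range search over translations at the coarsest level
    # (the MI landscape has voxel-periodic local optima)
    if (lv == levels) {
      steps <- scale_t * (-2:2)
      best <- list(val = neg_mi(p), d = c(0, 0, 0))
      for (dx in steps) for (dy in steps) for (dz in steps) {
        q <- p
        q[4:6] <- q[4:6] + c(dx, dy, dz)
        val <- neg_mi(q)
        if (val < best$val) best <- list(val = val, d = c(dx, dy, dz))
      }
      p[4:6] <- p[4:6] + best$d
    }
    # translation-only pre-alignment, then the full 7 degrees of freedom,
    # restarting Nelder-Mead once from its own optimum
    neg_mi_t <- function(tp) neg_mi(c(p[1:3], tp, p[7]))
    p[4:6] <- stats::optim(p[4:6], neg_mi_t, method = "Nelder-Mead",
                           control = list(maxit = 300, reltol = 1e-10,
                                          parscale = rep(scale_t, 3)))$par
    for (rs in 1:2) {
      opt <- stats::optim(p, neg_mi, method = "Nelder-Mead",
                          control = list(maxit = 600, reltol = 1e-12,
                                         parscale = c(rep(0.02, 3),
                                                      rep(scale_t, 3), 0.02)))
      p <- opt$par
    }
  }
  out <- params_to_similarity(p)
  # compare initial and final MI on the finest level with one shared sample
  f1 <- pyr_f[[1]]
  m1 <- pyr_m[[1]]
  pts1 <- informative_points(f1)
  pts1 <- pts1[sample.int(nrow(pts1), min(nrow(pts1), max_samples)), ,
               drop = FALSE]
  fv1 <- sample_volume_cpp(as.numeric(f1$data), dim(f1$data),
                           world_to_voxel(f1, pts1), 1L)$values
  mi_at <- function(tr) {
    q <- world_to_voxel(m1, apply_transform(tr, pts1))
    r <- sample_volume_cpp(as.numeric(m1$data), dim(m1$data), q, 1L)
    if (sum(!r$oob) < 100) return(-Inf)
    mutual_information(fv1[!r$oob], r$values[!r$oob], bins)
  }
  mi0 <- mi_at(init)
  mi1 <- mi_at(out)
  if (is.na(mi1) || mi1 < mi0) {
    out <- init
    mi1 <- mi0
  }
  attr(out, "mi_initial") <- mi0
  attr(out, "mi_final") <- mi1
  out
}

rot_params <- function(R) {
  # Euler angles (x, y, z convention matching euler_to_rotation)
  ry <- asin(pmin(pmax(-R[3, 1], -1), 1))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz)
}

volume_pyramid <- function(volume, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- volume
  for (lv in seq_len(levels - 1)) pyr[[lv + 1]] <- downsample2(pyr[[lv]])
  pyr
}

downsample2 <- function(volume) {
  d <- dim(volume$data)
  nd <- pmax(d %/% 2L, 1L)
  sm <- blur_volume(volume, 0.5 * volume$spacing * 2)
  idx <- lapply(1:3, function(a) pmin(2L * seq_len(nd[a]) - 1L, d[a]))
  data <- sm$data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  aff <- volume$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * 2
  image_volume(array(data, nd), affine = aff)
}

informative_points <- function(volume) {
  thr <- quantile(volume$data, 0.5)
  idx <- which(volume$data > thr)
  if (length(idx) < 500) idx <- seq_along(volume$data)
  d <- dim(volume$data)
  i <- (idx - 1) %% d[1]
  j <- ((idx - 1) %/% d[1]) %% d[2]
  k <- (idx - 1) %/% (d[1] * d[2])
  voxel_to_world(volume, cbind(i, j, k))
}

mutual_information <- function(a, b, bins) {
  ra <- range(a); rb <- range(b)
  if (diff(ra) < 1e-12 || diff(rb) < 1e-12) return(0)
  ia <- pmin(floor((a - ra[1]) / diff(ra) * bins) + 1, bins)
  ib <- pmin(floor((b - rb[1]) / diff(rb) * bins) + 1, bins)
  joint <- tabulate((ib - 1L) * bins + ia, nbins = bins * bins)
  p <- joint / sum(joint)
  pm <- matrix(p, bins, bins)
  pa <- rowSums(pm); pb <- colSums(pm)
  nz <- pm > 0
  sum(pm[nz] * log(pm[nz] / (pa[row(pm)[nz]] * pb[col(pm)[nz]])))
}

# --- surface registration ---------------------------------------------------

# Umeyama similarity alignment of paired points: finds s, R, t minimising
# ||s R x + t - y||^2.
umeyama <- function(x, y, with_scale = TRUE) {
  mx <- colMeans(x); my <- colMeans(y)
  xc <- sweep(x, 2, mx); yc <- sweep(y, 2, my)
  S <- crossprod(yc, xc) / nrow(x)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  varx <- mean(rowSums(xc^2))
  s <- if (with_scale) sum(sv$d * c(1, 1, d)) / varx else 1
  t <- my - s * as.numeric(R %*% mx)
  similarity_transform(R, t, s)
}

#' Thin-plate-spline transform from control-point correspondences
#'
#' 3D polyharmonic spline with kernel `U(r) = r` plus an affine part, the
#' standard minimal-bending-energy interpolant.  At `lambda = 0` the map
#' interpolates the control points exactly; larger `lambda` trades fidelity
#' for smoothness.
#'
#' @param source,target n x 3 matrices of corresponding points (n >= 4,
#'   non-coplanar).
#' @param lambda regularisation (>= 0, default 0).
#' @return A `tps_transform`.
#' @export
tps_transform <- function(source, target, lambda = 0) {
  x <- as.matrix(source); y <- as.matrix(target)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 control points")
  K <- as.matrix(stats::dist(x))
  P <- cbind(1, x)
  if (abs(det(crossprod(P))) < 1e-10)
    stop("degenerate (coplanar or coincident) control points")
  A <- rbind(cbind(K + lambda * diag(n), P),
             cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(y, matrix(0, 4, 3))
  coef <- solve(A, rhs)
  structure(list(control_points = x, weights = coef[seq_len(n), , drop = FALSE],
                 affine = coef[n + 1:4, , drop = FALSE], lambda = lambda),
            class = "tps_transform")
}

#' @export
apply_transform.tps_transform <- function(transform, pts) {
  pts <- as.matrix(pts)
  d2 <- outer(rowSums(pts^2), rep(1, nrow(transform$control_points))) +
    outer(rep(1, nrow(pts)), rowSums(transform$control_points^2)) -
    2 * pts %*% t(transform$control_points)
  U <- sqrt(pmax(d2, 0))
  cbind(1, pts) %*% transform$affine + U %*% transform$weights
}

# TPS bending energy (quadratic form in the radial weights).
tps_bending_energy <- function(tps) {
  K <- as.matrix(stats::dist(tps$control_points))
  sum(diag(t(tps$weights) %*% K %*% tps$weights))
}

#' Register one surface onto another (similarity then thin plate spline)
#'
#' Stage 1 is iterative-closest-point alignment with isotropic scale; stage 2
#' fits a regularised thin plate spline on a farthest-point subsample of the
#' converged correspondences, bending the source surface onto the target.
#' The residual after the TPS stage never exceeds the similarity-stage
#' residual.
#'
#' @param source,target [triangle_mesh] or `joint_space_patch` objects of
#'   comparable anatomy and extent.
#' @param n_control TPS control points (default 200).
#' @param lambda TPS regularisation (default 0.01).
#' @param max_iter,tol ICP iteration cap and relative convergence tolerance.
#' @return A `surface_registration`: list with `similarity`, `tps`,
#'   `residual_similarity`, `residual_tps` (mean point-to-surface distances,
#'   mm).
#' @export
register_surfaces <- function(source, target, n_control = 200, lambda = 0.01,
                              max_iter = 50, tol = 1e-10) {
  sv <- if (inherits(source, "joint_space_patch")) source$mesh else source
  tv <- if (inherits(target, "joint_space_patch")) target$mesh else target
  x <- sv$vertices
  y <- tv$vertices
  # multi-start ICP: centroid/RMS-radius init plus principal-axis inits
  # (all proper sign combinations), keeping the lowest-residual pose
  s0 <- sqrt(mean(rowSums(sweep(y, 2, colMeans(y))^2)) /
             mean(rowSums(sweep(x, 2, colMeans(x))^2)))
  inits <- list(similarity_transform(diag(3), colMeans(y) - s0 * colMeans(x), s0))
  Vx <- eigen(stats::cov(x), symmetric = TRUE)$vectors
  Vy <- eigen(stats::cov(y), symmetric = TRUE)$vectors
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    D <- diag(c(s1, s2, s1 * s2 * sign(det(Vy %*% t(Vx)))))
    R0 <- Vy %*% D %*% t(Vx)
    if (det(R0) < 0) next
    inits <- c(inits, list(similarity_transform(
      R0, colMeans(y) - s0 * as.numeric(R0 %*% colMeans(x)), s0)))
  }
  best <- NULL
  for (tr0 in inits) {
    run <- icp_with_scale(x, y, tr0, max_iter, tol)
    if (is.null(best) || run$res < best$res) best <- run
  }
  tr <- best$tr
  xt <- apply_transform(tr, x)
  res_sim <- mean(point_mesh_dist_cpp(xt, tv$vertices, tv$triangles))
  ctrl_idx <- farthest_point_sample(xt, min(n_control, nrow(xt)))
  ctrl <- xt[ctrl_idx, , drop = FALSE]
  corr <- tv$vertices[nn_index_cpp(ctrl, tv$vertices)$index, , drop = FALSE]
  tps <- tps_transform(ctrl, corr, lambda = lambda)
  xw <- apply_transform(tps, xt)
  res_tps <- mean(point_mesh_dist_cpp(xw, tv$vertices, tv$triangles))
  if (res_tps > res_sim) {
    tps <- tps_transform(ctrl, ctrl, lambda = 0)  # identity warp
    res_tps <- res_sim
  }
  structure(list(similarity = tr, tps = tps, residual_similarity = res_sim,
                 residual_tps = res_tps),
            class = "surface_registration")
}

#' @export
apply_transform.surface_registration <- function(transform, pts) {
  apply_transform(transform$tps, apply_transform(transform$similarity, pts))
}

#' @export
print.surface_registration <- function(x, ...) {
  cat(sprintf("surface_registration: residual %.4f mm (similarity) -> %.4f mm (TPS)\n",
              x$residual_similarity, x$residual_tps))
  invisible(x)
}

icp_with_scale <- function(x, y, tr, max_iter, tol) {
  prev <- Inf
  res <- Inf
  for (it in seq_len(max_iter)) {
    xt <- apply_transform(tr, x)
    nn <- nn_index_cpp(xt, y)
    tr <- umeyama(x, y[nn$index, , drop = FALSE])
    res <- mean(nn$dist)
    if (is.finite(prev) && abs(prev - res) < tol * max(prev, 1e-12)) break
    prev <- res
  }
  list(tr = tr, res = res)
}

farthest_point_sample <- function(pts, n) {
  m <- nrow(pts)
  if (n >= m) return(seq_len(m))
  sel <- integer(n)
  sel[1] <- 1L
  d <- sqrt(rowSums(sweep(pts, 2, pts[1, ])^2))
  for (k in 2:n) {
    sel[k] <- which.max(d)
    d <- pmin(d, sqrt(rowSums(sweep(pts, 2, pts[sel[k], ])^2)))
  }
  sel
}

#' Transfer per-vertex values onto an average surface
#'
#' Each average-surface vertex takes the value of the nearest transformed
#' source vertex; an optional uniform Laplacian smoothing pass follows.
#' Missing source values stay missing, and smoothing is a convex
#' combination, so no new extrema are created.
#'
#' @param values numeric per-vertex values on the source surface.
#' @param source_surface the source [triangle_mesh] (or patch).
#' @param transform any transform accepted by [apply_transform()] mapping the
#'   source onto the average surface (use `NULL` for none).
#' @param average_surface the target [triangle_mesh] (or patch).
#' @param smooth_iterations smoothing passes after transfer (default 1).
#' @return numeric vector of values on the average surface.
#' @export
transfer_values <- function(values, source_surface, transform,
                            average_surface, smooth_iterations = 1) {
  sm <- if (inherits(source_surface, "joint_space_patch")) source_surface$mesh
        else source_surface
  am <- if (inherits(average_surface, "joint_space_patch")) average_surface$mesh
        else average_surface
  src <- sm$vertices
  if (!is.null(transform)) src <- apply_transform(transform, src)
  nn <- nn_index_cpp(am$vertices, src)$index
  out <- values[nn]
  if (smooth_iterations > 0) {
    adj <- vertex_adjacency(am)
    for (it in seq_len(smooth_iterations)) {
      new <- out
      for (i in seq_along(out)) {
        if (!is.finite(out[i])) next
        nb <- adj[[i]]
        v <- out[nb]
        v <- v[is.finite(v)]
        if (length(v)) new[i] <- 0.5 * out[i] + 0.5 * mean(v)
      }
      out <- new
    }
  }
  out
}

#' Build an average joint surface from a set of registered surfaces
#'
#' A reference surface (the first contributor, re-triangulated to the target
#' vertex count) is refined by repeatedly registering every contributor to
#' it, replacing each reference vertex by the mean of its nearest
#' correspondent on each contributor, and smoothing (shape-preserving Taubin
#' passes in the interior, Laplacian passes along the boundary).
#'
#' @param surfaces list of [triangle_mesh] / `joint_space_patch` objects
#'   (>= 2).
#' @param target_vertex_count vertex count of the average surface (default
#'   2300, the conventional display resolution).
#' @param iterations refinement iterations (default 2).
#' @param boundary_smooth Laplacian passes along the boundary (default 5).
#' @param interior_smooth Taubin passes in the interior (default 3).
#' @return An `average_surface`: list with `mesh` and `provenance`.
#' @export
build_average_surface <- function(surfaces, target_vertex_count = 2300,
                                  iterations = 2, boundary_smooth = 5,
                                  interior_smooth = 3) {
  if (length(surfaces) < 2) stop("need at least 2 surfaces")
  meshes <- lapply(surfaces, function(s)
    if (inherits(s, "joint_space_patch")) s$mesh else s)
  ref <- retriangulate(meshes[[1]], target_vertex_count)$mesh
  for (it in seq_len(iterations)) {
    acc <- matrix(0, nrow(ref$vertices), 3)
    for (si in seq_along(meshes)) {
      m <- meshes[[si]]
      reg <- tryCatch(register_surfaces(ref, m),
                      error = function(e)
                        stop("registration failed for surface ", si, ": ",
                             conditionMessage(e)))
      # registration supplies the correspondence; averaging happens in the
      # world frame so no contributor's pose is privileged
      fwd <- apply_transform(reg, ref$vertices)
      corr <- m$vertices[nn_index_cpp(fwd, m$vertices)$index, , drop = FALSE]
      acc <- acc + corr
    }
    ref <- triangle_mesh(acc / length(meshes), ref$triangles)
    bnd <- boundary_vertices(ref)
    interior <- setdiff(seq_len(nrow(ref$vertices)), bnd)
    if (interior_smooth > 0) {
      mv <- rep(FALSE, nrow(ref$vertices))
      mv[interior] <- TRUE
      ref <- taubin_smooth(ref, interior_smooth, move = mv)
    }
    if (boundary_smooth > 0 && length(bnd) > 2)
      ref <- smooth_boundary(ref, bnd, boundary_smooth)
  }
  structure(list(mesh = ref,
                 provenance = names(surfaces) %||%
                   paste0("surface_", seq_along(surfaces))),
            class = "average_surface")
}

# Laplacian smoothing of boundary vertices along the boundary curve only,
# in shrink-compensated (Taubin) forward/backward pairs so smooth loops are
# left essentially in place.
smooth_boundary <- function(mesh, bnd, passes, lambda = 0.5, mu = -0.53) {
  loops <- boundary_loops(mesh)
  v <- mesh$vertices
  for (loop in loops) {
    nl <- length(loop)
    if (nl < 3) next
    step_once <- function(v, f) {
      prev <- v[loop[c(nl, seq_len(nl - 1))], , drop = FALSE]
      nxt <- v[loop[c(seq_len(nl - 1) + 1, 1)], , drop = FALSE]
      v[loop, ] <- v[loop, , drop = FALSE] +
        f * ((prev + nxt) / 2 - v[loop, , drop = FALSE])
      v
    }
    for (p in seq_len(passes)) {
      v <- step_once(v, lambda)
      v <- step_once(v, mu)
    }
  }
  triangle_mesh(v, mesh$triangles)
}

#' @export
print.average_surface <- function(x, ...) {
  cat("average_surface:", nrow(x$mesh$vertices), "vertices from",
      length(x$provenance), "contributors\n")
  invisible(x)
}

#' Serialise a transform to JSON
#' @param transform a `similarity_transform` or `surface_registration`.
#' @param path output JSON path.
#' @export
write_transform <- function(transform, path) {
  obj <- if (inherits(transform, "similarity_transform")) {
    list(type = "similarity", rotation = transform$rotation,
         translation = transform$translation, scale = transform$scale)
  } else if (inherits(transform, "surface_registration")) {
    list(type = "surface_registration",
         similarity = list(rotation = transform$similarity$rotation,
                           translation = transform$similarity$translation,
                           scale = transform$similarity$scale),
         tps = list(control_points = transform$tps$control_points,
                    weights = transform$tps$weights,
                    affine = transform$tps$affine,
                    lambda = transform$tps$lambda))
  } else stop("unsupported transform type")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
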