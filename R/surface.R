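#' Extract a bone surface mesh from a binary mask
#'
#' The mask is pre-smoothed with a 1-voxel Gaussian and the isosurface at
#' `iso_level` is extracted with marching tetrahedra; the largest connected
#' component is kept and lightly regularised.  Vertices are returned in world
#' mm with outward per-vertex normals (pointing from mask interior to
#' exterior).  Downstream joint space measurement tolerates surface error of
#' up to +/-2 mm, so the precise meshing scheme is not critical.
#'
#' @param mask_volume an [image_volume] holding a binary (0/1) mask.
#' @param iso_level isosurface level on the smoothed mask (default 0.5).
#' @param presmooth_vox Gaussian pre-smoothing SD in voxels (default 1).
#' @param smooth_iterations Taubin regularisation iterations on the extracted
#'   mesh (default 10).
#' @return A [triangle_mesh].
#' @export
mesh_from_mask <- function(mask_volume, iso_level = 0.5, presmooth_vox = 1,
                           smooth_iterations = 10) {
  if (max(mask_volume$data) <= 0) stop("mask is empty")
  sm <- blur_volume(mask_volume, presmooth_vox * mask_volume$spacing)
  res <- march_tets_cpp(as.numeric(sm$data), dim(sm$data), iso_level)
  if (nrow(res$vertices) == 0L) stop("no isosurface found at iso_level")
  comp <- largest_component(res$vertices, res$triangles)
  vw <- voxel_to_world(mask_volume, comp$vertices)
  mesh <- triangle_mesh(vw, comp$triangles)
  if (smooth_iterations > 0) mesh <- taubin_smooth(mesh, smooth_iterations)
  mesh
}

#' Project opposing bone density onto a surface
#'
#' For each vertex, the maximum interpolated HU along the outward normal over
#' `(0, search_depth]` mm.  Where opposing bone lies within reach this yields
#' a bright patch whose perimeter is the joint space margin.
#'
#' @param mesh a [triangle_mesh] (the femoral surface).
#' @param volume the CT [image_volume].
#' @param search_depth search extent in mm along each normal (default 5).
#' @param step sampling step in mm (default 0.2).
#' @param interp interpolation scheme, see [sample_profile()].
#' @return numeric vector, one max-HU value per vertex.
#' @export
project_opposing_bone <- function(mesh, volume, search_depth = 5, step = 0.2,
                                  interp = c("cubic", "linear")) {
  interp <- match.arg(interp)
  if (search_depth <= 0) stop("search_depth must be positive")
  tt <- seq(step, search_depth, by = step)
  nv <- nrow(mesh$vertices)
  pts <- matrix(0, nv * length(tt), 3)
  for (i in seq_along(tt)) {
    pts[(i - 1) * nv + seq_len(nv), ] <- mesh$vertices + tt[i] * mesh$normals
  }
  vox <- world_to_voxel(volume, pts)
  res <- sample_volume_cpp(as.numeric(volume$data), dim(volume$data), vox,
                           if (interp == "cubic") 3L else 1L)
  vals <- matrix(res$values, nrow = nv)
  apply(vals, 1, max)
}

#' Cut the joint space patch from a bone mesh along a boundary polyline
#'
#' The polyline (closed loop of world points on or near the surface) is
#' snapped to mesh vertices, joined by shortest paths along mesh edges, and
#' the enclosed region is recovered by flood fill with the boundary vertices
#' removed.  The side kept is the one containing `seed` (world point), or
#' the side with the higher mean of `values` (e.g. the opposing-bone
#' projection) when no seed is given.
#'
#' @param mesh a [triangle_mesh].
#' @param boundary_polyline k x 3 matrix of world points; the first and last
#'   rows must coincide (closed loop).
#' @param seed optional world point selecting the side to keep.
#' @param values optional per-vertex scalar used to select the side when
#'   `seed` is missing.
#' @param snap_dist maximum snap distance from polyline points to the mesh
#'   (mm, default 5).
#' @return A `joint_space_patch`: list with `mesh`, `boundary` (ordered loop
#'   of boundary vertex indices into the patch mesh) and `source_id`.
#' @export
cut_patch <- function(mesh, boundary_polyline, seed = NULL, values = NULL,
                      snap_dist = 5, source_id = "patch") {
  bp <- as.matrix(boundary_polyline)
  if (nrow(bp) < 4) stop("boundary polyline too short")
  if (sqrt(sum((bp[1, ] - bp[nrow(bp), ])^2)) > 1e-6)
    stop("boundary polyline must be a closed loop (first point == last point)")
  bp <- bp[-nrow(bp), , drop = FALSE]
  nn <- nn_index_cpp(bp, mesh$vertices)
  if (max(nn$dist) > snap_dist)
    stop("boundary polyline cannot be snapped to the mesh (max distance ",
         round(max(nn$dist), 2), " mm)")
  snapped <- nn$index
  snapped <- snapped[c(TRUE, diff(snapped) != 0L)]
  if (length(snapped) > 1 && snapped[1] == snapped[length(snapped)])
    snapped <- snapped[-length(snapped)]
  if (anyDuplicated(snapped))
    stop("boundary polyline is self-intersecting after snapping")
  ed <- mesh_edges(mesh)$edges
  elen <- sqrt(rowSums((mesh$vertices[ed[, 1], , drop = FALSE] -
                        mesh$vertices[ed[, 2], , drop = FALSE])^2))
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  igraph::E(g)$weight <- elen
  loop <- integer(0)
  ns <- length(snapped)
  for (i in seq_len(ns)) {
    from <- snapped[i]
    to <- snapped[if (i == ns) 1L else i + 1L]
    sp <- igraph::shortest_paths(g, from, to, output = "vpath")$vpath[[1]]
    sp <- as.integer(sp)
    if (length(sp) == 0) stop("boundary loop is not connected on the mesh")
    loop <- c(loop, sp[-length(sp)])
  }
  if (anyDuplicated(loop))
    stop("boundary polyline is self-intersecting after snapping")
  other <- setdiff(seq_len(nrow(mesh$vertices)), loop)
  g2 <- igraph::delete_vertices(g, loop)
  memb <- igraph::components(g2)$membership
  memb_full <- rep(NA_integer_, nrow(mesh$vertices))
  memb_full[other] <- memb
  ncomp <- max(memb, 0L)
  pick <- if (ncomp <= 1L) {
    1L
  } else if (!is.null(seed)) {
    sv <- nn_index_cpp(matrix(seed, 1), mesh$vertices)$index
    if (is.na(memb_full[sv])) stop("seed point snapped onto the boundary loop")
    memb_full[sv]
  } else if (!is.null(values)) {
    means <- tapply(values[other], memb, mean)
    as.integer(names(which.max(means)))
  } else {
    stop("multiple regions: provide `seed` or `values` to choose a side")
  }
  keep <- sort(c(loop, other[memb == pick]))
  tri_keep <- mesh$triangles[
    rowSums(matrix(mesh$triangles %in% keep, ncol = 3)) == 3L, , drop = FALSE]
  cl <- clean_mesh(mesh$vertices, tri_keep)
  remap <- integer(nrow(mesh$vertices))
  remap[cl$kept] <- seq_along(cl$kept)
  pmesh <- triangle_mesh(cl$vertices, cl$triangles)
  # carry outward normals orientation from the parent mesh
  pmesh$normals <- orient_like(pmesh, mesh$normals[cl$kept, , drop = FALSE])
  bnd <- remap[loop]
  bnd <- bnd[bnd > 0]
  structure(list(mesh = pmesh, boundary = bnd, source_id = source_id),
            class = "joint_space_patch")
}

# Flip recomputed normals that disagree with reference normals (open patches
# can lose global orientation cues after cutting).
orient_like <- function(mesh, ref_normals) {
  n <- mesh$normals
  flip <- rowSums(n * ref_normals) < 0
  if (mean(flip) > 0.5) n <- -n
  n
}

#' @export
print.joint_space_patch <- function(x, ...) {
  cat("joint_space_patch:", nrow(x$mesh$vertices), "vertices,",
      length(x$boundary), "boundary vertices (", x$source_id, ")\n")
  invisible(x)
}

# Midpoint (1-to-4) subdivision; boundary midpoints stay on the boundary
# segments so the boundary curve is preserved exactly.
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  ed <- mesh_edges(mesh)$edges
  key <- paste(ed[, 1], ed[, 2])
  mid_idx <- nrow(v) + seq_len(nrow(ed))
  names(mid_idx) <- key
  mids <- (v[ed[, 1], , drop = FALSE] + v[ed[, 2], , drop = FALSE]) / 2
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  m12 <- mid_idx[ekey(tr[, 1], tr[, 2])]
  m23 <- mid_idx[ekey(tr[, 2], tr[, 3])]
  m31 <- mid_idx[ekey(tr[, 3], tr[, 1])]
  newtr <- rbind(cbind(tr[, 1], m12, m31),
                 cbind(m12, tr[, 2], m23),
                 cbind(m31, m23, tr[, 3]),
                 cbind(m12, m23, m31))
  triangle_mesh(rbind(v, mids), newtr)
}

# Greedy shortest-edge collapse decimation towards a target vertex count,
# keeping vertex density roughly uniform.  Interior-interior edges collapse
# to their midpoint; interior-boundary edges collapse the interior vertex
# onto the boundary one; boundary edges collapse along the boundary curve
# (so boundary vertices always remain a subset of the original curve).  A
# link-condition check avoids creating non-manifold fins.
decimate_mesh <- function(mesh, target) {
  repeat {
    nv <- nrow(mesh$vertices)
    if (nv <= target) break
    ed <- mesh_edges(mesh)
    e <- ed$edges
    cnt <- ed$count
    is_bnd <- logical(nv)
    is_bnd[unique(as.vector(e[cnt == 1L, , drop = FALSE]))] <- TRUE
    len <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                         mesh$vertices[e[, 2], , drop = FALSE])^2))
    ord <- order(len)
    adj <- vertex_adjacency(mesh)
    touched <- logical(nv)
    budget <- nv - target
    keep <- drop <- integer(0)
    mid <- logical(0)
    for (idx in ord) {
      a <- e[idx, 1]; b <- e[idx, 2]
      if (touched[a] || touched[b]) next
      nb_common <- length(intersect(adj[[a]], adj[[b]]))
      ab_bnd <- c(is_bnd[a], is_bnd[b])
      if (all(ab_bnd)) {
        if (cnt[idx] != 1L || nb_common != 1L) next  # only true boundary edges
        k <- a; d <- b; m <- FALSE
      } else if (any(ab_bnd)) {
        if (nb_common != 2L) next
        k <- if (ab_bnd[1]) a else b
        d <- if (ab_bnd[1]) b else a
        m <- FALSE
      } else {
        if (nb_common != 2L) next
        k <- a; d <- b; m <- TRUE
      }
      touched[adj[[a]]] <- TRUE
      touched[adj[[b]]] <- TRUE
      touched[a] <- TRUE; touched[b] <- TRUE
      keep <- c(keep, k); drop <- c(drop, d); mid <- c(mid, m)
      budget <- budget - 1L
      if (budget <= 0L) break
    }
    if (length(keep) == 0L) break
    v <- mesh$vertices
    map <- seq_len(nv)
    if (any(mid))
      v[keep[mid], ] <- (v[keep[mid], , drop = FALSE] +
                           v[drop[mid], , drop = FALSE]) / 2
    map[drop] <- keep
    tr <- matrix(map[mesh$triangles], ncol = 3)
    cl <- clean_mesh(v, tr)
    mesh <- triangle_mesh(cl$vertices, cl$triangles)
  }
  mesh
}

#' Re-triangulate a joint space patch to a target vertex count
#'
#' The patch is refined by midpoint subdivision and decimated by greedy
#' shortest-edge collapse of interior edges until the vertex count is close
#' to `target_vertex_count`.  Boundary vertices stay exactly on the original
#' boundary curve.  Joint space patches are conventionally re-triangulated to
#' about 4,000 vertices so profile sampling does not undersample the data.
#'
#' @param patch a `joint_space_patch` (or bare [triangle_mesh]).
#' @param target_vertex_count desired vertex count (minimum 100).
#' @return A `joint_space_patch` with vertex count within about +/-10% of the
#'   target.
#' @export
retriangulate <- function(patch, target_vertex_count = 4000) {
  if (target_vertex_count < 100) stop("target_vertex_count must be >= 100")
  mesh <- if (inherits(patch, "joint_space_patch")) patch$mesh else patch
  src_normals <- mesh$normals
  src_vertices <- mesh$vertices
  while (nrow(mesh$vertices) < target_vertex_count) mesh <- subdivide_mesh(mesh)
  if (nrow(mesh$vertices) > target_vertex_count)
    mesh <- decimate_mesh(mesh, target_vertex_count)
  # re-orient normals consistently with the source surface
  nn <- nn_index_cpp(mesh$vertices, src_vertices)$index
  mesh$normals <- orient_like(mesh, src_normals[nn, , drop = FALSE])
  loops <- boundary_loops(mesh)
  bnd <- if (length(loops)) loops[[which.max(lengths(loops))]] else integer(0)
  structure(list(mesh = mesh, boundary = bnd,
                 source_id = if (inherits(patch, "joint_space_patch"))
                   patch$source_id else "mesh"),
            class = "joint_space_patch")
}
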