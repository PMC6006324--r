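#' Triangle mesh container
#'
#' Vertices in world mm, 1-based triangle indices, and per-vertex outward
#' unit normals.  Winding is consistent: triangle normals point away from the
#' bone interior.
#'
#' @param vertices n x 3 numeric matrix.
#' @param triangles m x 3 integer matrix (1-based).
#' @param normals optional n x 3 matrix; recomputed from the triangulation
#'   when omitted.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, normals = NULL) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (ncol(vertices) != 3L) stop("vertices must be n x 3")
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  m <- structure(list(vertices = vertices, triangles = triangles,
                      normals = normals), class = "triangle_mesh")
  if (is.null(normals)) m$normals <- vertex_normals(m)
  m
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$triangles), "triangles\n")
  invisible(x)
}

triangle_cross <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  u <- v[tr[, 2], , drop = FALSE] - a
  w <- v[tr[, 3], , drop = FALSE] - a
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

#' Total surface area of a mesh in mm^2
#' @param mesh a [triangle_mesh].
#' @export
mesh_area <- function(mesh) sum(sqrt(rowSums(triangle_cross(mesh)^2))) / 2

#' Per-vertex outward unit normals (area-weighted average of incident
#' triangle normals).
#' @param mesh a [triangle_mesh].
#' @return n x 3 matrix of unit vectors.
#' @export
vertex_normals <- function(mesh) {
  cr <- triangle_cross(mesh)  # length = 2 * area, direction = winding normal
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (c in 1:3) {
    for (col in 1:3) {
      acc <- rowsum(cr[, col], mesh$triangles[, c])
      idx <- as.integer(rownames(acc))
      n[idx, col] <- n[idx, col] + acc[, 1]
    }
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-12] <- 1
  n / len
}

# Unique undirected edges as a 2-column matrix, plus per-edge triangle count.
mesh_edges <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  tab <- table(key)
  uniq <- !duplicated(key)
  list(edges = e[uniq, , drop = FALSE],
       count = as.integer(tab[key[uniq]]))
}

#' Boundary vertices of an open mesh
#'
#' Vertices incident to an edge used by exactly one triangle.
#' @param mesh a [triangle_mesh].
#' @return integer vector of vertex indices (unordered).
#' @export
boundary_vertices <- function(mesh) {
  ed <- mesh_edges(mesh)
  sort(unique(as.vector(ed$edges[ed$count == 1L, , drop = FALSE])))
}

# Ordered boundary loop(s); returns list of integer vectors.
boundary_loops <- function(mesh) {
  ed <- mesh_edges(mesh)
  be <- ed$edges[ed$count == 1L, , drop = FALSE]
  if (nrow(be) == 0L) return(list())
  g <- igraph::graph_from_edgelist(be, directed = FALSE)
  comps <- igraph::components(g)
  used <- which(igraph::degree(g) > 0)
  loops <- list()
  for (cc in seq_len(comps$no)) {
    vs <- intersect(which(comps$membership == cc), used)
    if (length(vs) < 3) next
    sub <- igraph::induced_subgraph(g, vs)
    ord <- as.integer(igraph::V(sub)$name %||% vs)
    # walk the cycle
    adj <- lapply(igraph::adjacent_vertices(g, vs), as.integer)
    names(adj) <- vs
    start <- vs[1]
    loop <- start
    prev <- NA_integer_
    cur <- start
    repeat {
      nb <- adj[[as.character(cur)]]
      nxt <- setdiff(nb, prev)[1]
      if (is.na(nxt) || nxt == start) break
      loop <- c(loop, nxt)
      prev <- cur
      cur <- nxt
      if (length(loop) > length(vs)) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Vertex adjacency list from the triangulation.
vertex_adjacency <- function(mesh) {
  ed <- mesh_edges(mesh)$edges
  adj <- vector("list", nrow(mesh$vertices))
  sp1 <- split(ed[, 2], ed[, 1])
  sp2 <- split(ed[, 1], ed[, 2])
  for (k in names(sp1)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp1[[k]])
  for (k in names(sp2)) adj[[as.integer(k)]] <- c(adj[[as.integer(k)]], sp2[[k]])
  adj
}

# Remove triangles with repeated vertices and drop unreferenced vertices.
clean_mesh <- function(vertices, triangles, carry = NULL) {
  ok <- triangles[, 1] != triangles[, 2] & triangles[, 2] != triangles[, 3] &
    triangles[, 1] != triangles[, 3]
  triangles <- triangles[ok, , drop = FALSE]
  # drop exact duplicate faces (same vertex set)
  key <- apply(triangles, 1, function(r) paste(sort(r), collapse = " "))
  triangles <- triangles[!duplicated(key), , drop = FALSE]
  used <- sort(unique(as.vector(triangles)))
  remap <- integer(nrow(vertices))
  remap[used] <- seq_along(used)
  out <- list(vertices = vertices[used, , drop = FALSE],
              triangles = matrix(remap[triangles], ncol = 3),
              kept = used)
  if (!is.null(carry)) out$carry <- lapply(carry, function(x) x[used])
  out
}

# Keep the largest connected component (by triangle count).
largest_component <- function(vertices, triangles) {
  g <- igraph::graph_from_edgelist(
    rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)]),
    directed = FALSE)
  memb <- igraph::components(g)$membership
  tri_comp <- memb[triangles[, 1]]
  keep <- tri_comp == as.integer(names(which.max(table(tri_comp))))
  clean_mesh(vertices, triangles[keep, , drop = FALSE])
}

# Taubin lambda/mu smoothing (approximately shrink-free); `move` restricts
# which vertices may move.
taubin_smooth <- function(mesh, iterations = 5, lambda = 0.33, mu = -0.34,
                          move = NULL) {
  v <- mesh$vertices
  nv <- nrow(v)
  ed <- mesh_edges(mesh)$edges
  i <- c(ed[, 1], ed[, 2])
  j <- c(ed[, 2], ed[, 1])
  deg <- tabulate(i, nv)
  deg[deg == 0] <- 1
  if (is.null(move)) move <- rep(TRUE, nv)
  step_once <- function(v, f) {
    acc <- rowsum(v[j, , drop = FALSE], i, reorder = TRUE)
    nbr <- v
    idx <- as.integer(rownames(acc))
    nbr[idx, ] <- acc / deg[idx]
    d <- f * (nbr - v)
    d[!move, ] <- 0
    v + d
  }
  for (it in seq_len(iterations)) {
    v <- step_once(v, lambda)
    v <- step_once(v, mu)
  }
  triangle_mesh(v, mesh$triangles)
}

#' Read/write triangle meshes as ASCII PLY or OBJ
#'
#' @param path file path (`.ply` or `.obj`).
#' @return For `read_mesh`, a [triangle_mesh].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  lines <- readLines(path)
  if (ext == "obj") {
    vl <- lines[startsWith(lines, "v ")]
    fl <- lines[startsWith(lines, "f ")]
    v <- do.call(rbind, lapply(strsplit(vl, " +"), function(x) as.numeric(x[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, " +"), function(x)
      as.integer(sub("/.*", "", x[2:4]))))
    return(triangle_mesh(v, f))
  }
  if (ext == "ply") {
    nv <- as.integer(sub(".*vertex ", "", grep("element vertex", lines, value = TRUE)[1]))
    nf <- as.integer(sub(".*face ", "", grep("element face", lines, value = TRUE)[1]))
    hdr_end <- which(lines == "end_header")[1]
    vdat <- do.call(rbind, lapply(strsplit(trimws(lines[hdr_end + seq_len(nv)]), " +"),
                                  as.numeric))
    fdat <- do.call(rbind, lapply(strsplit(trimws(lines[hdr_end + nv + seq_len(nf)]), " +"),
                                  as.numeric))
    return(triangle_mesh(vdat[, 1:3, drop = FALSE], fdat[, 2:4, drop = FALSE] + 1L))
  }
  stop("unsupported mesh format: ", ext)
}

#' @rdname read_mesh
#' @param mesh a [triangle_mesh].
#' @param scalars optional named list of per-vertex numeric attributes
#'   (written as extra PLY properties).
#' @export
write_mesh <- function(mesh, path, scalars = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1], mesh$vertices[, 2],
                       mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", mesh$triangles[, 1], mesh$triangles[, 2],
                       mesh$triangles[, 3]), con)
    return(invisible(path))
  }
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    props <- c("property double x", "property double y", "property double z")
    extra <- NULL
    if (!is.null(scalars)) {
      props <- c(props, sprintf("property double %s", names(scalars)))
      extra <- do.call(cbind, scalars)
    }
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(mesh$vertices)), props,
                 sprintf("element face %d", nrow(mesh$triangles)),
                 "property list uchar int vertex_indices", "end_header"), con)
    vdat <- if (is.null(extra)) mesh$vertices else cbind(mesh$vertices, extra)
    writeLines(apply(vdat, 1, function(r) paste(sprintf("%.9g", r), collapse = " ")), con)
    writeLines(sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                       mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L), con)
    return(invisible(path))
  }
  stop("unsupported mesh format: ", ext)
}

#' Two-sided (symmetric) Hausdorff-style distance between meshes
#'
#' Maximum over vertices of each mesh of the distance to the other mesh's
#' triangulated surface.
#' @param a,b [triangle_mesh] objects.
#' @export
mesh_hausdorff <- function(a, b) {
  d1 <- point_mesh_dist_cpp(a$vertices, b$vertices, b$triangles)
  d2 <- point_mesh_dist_cpp(b$vertices, a$vertices, a$triangles)
  max(max(d1), max(d2))
}
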