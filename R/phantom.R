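#' Synthetic two-bone phantom specification
#'
#' Parametric phantoms with analytic ground truth, used to validate every
#' stage of the pipeline.  Two geometries: `"ball_socket"` (a spherical
#' femoral head capped by a concentric acetabular shell over a polar cap,
#' leaving an uncovered region so boundary extraction is non-trivial) and
#' `"plates"` (two parallel cortical plates).  The continuous geometry is
#' voxelized with sub-voxel supersampling (partial volume), blurred by an
#' anisotropic Gaussian point spread function and corrupted with iid
#' Gaussian noise.
#'
#' Defaults emulate a clinical hip CT acquisition: 0.31 x 0.31 mm pixels
#' with 1.5 mm slices, an in-plane PSF of 0.87 mm and out-of-plane 1.00 mm
#' (interpreted as FWHM; set `psf_is_fwhm = FALSE` to read them as sigma),
#' noise SD 20 HU, cartilage-equivalent joint tissue at 35 HU and cortical
#' bone at 1400 HU.
#'
#' @param geometry `"ball_socket"` or `"plates"`.
#' @param femoral_radius outer femoral radius in mm (ball_socket).
#' @param cortex_thickness cortical plate/shell thickness per bone (mm).
#' @param gap constant joint space width (mm), or supply `gap_function`.
#' @param gap_function optional `function(theta, phi)` returning the gap in
#'   mm (angles in radians, theta from the pole).
#' @param densities named vector: `interior`, `cortex`, `joint_tissue`,
#'   `background`, `far` (HU).
#' @param psf per-axis Gaussian PSF (mm); FWHM when `psf_is_fwhm`.
#' @param psf_is_fwhm interpret `psf` as full width at half maximum.
#' @param noise_sd additive Gaussian noise SD (HU).
#' @param spacing voxel spacing (mm).
#' @param cap_angle polar extent of the acetabular shell (degrees).
#' @param boundary_angle polar angle of the joint-margin boundary loop
#'   (degrees; inside the cap).
#' @param plate_extent lateral half-extent of the plates geometry (mm).
#' @param supersample sub-voxel sampling factor for partial volume; a scalar
#'   or per-axis length-3 vector.
#' @param margin world-space padding around the geometry (mm).
#' @param seed RNG seed (noise and operator simulation).
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(geometry = c("ball_socket", "plates"),
                         femoral_radius = 20, cortex_thickness = 1.5,
                         gap = 3.0, gap_function = NULL,
                         densities = c(interior = 300, cortex = 1400,
                                       joint_tissue = 35, background = 50,
                                       far = 150),
                         psf = c(0.87, 0.87, 1.00), psf_is_fwhm = TRUE,
                         noise_sd = 20, spacing = c(0.31, 0.31, 1.5),
                         cap_angle = 60, boundary_angle = 50,
                         plate_extent = 12, supersample = 3, margin = 5,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (densities["cortex"] <= densities["joint_tissue"])
    stop("cortex density must exceed joint tissue density")
  spec <- structure(list(geometry = geometry, femoral_radius = femoral_radius,
                         cortex_thickness = cortex_thickness, gap = gap,
                         gap_function = gap_function, densities = densities,
                         psf = psf, psf_is_fwhm = psf_is_fwhm,
                         noise_sd = noise_sd, spacing = spacing,
                         cap_angle = cap_angle,
                         boundary_angle = boundary_angle,
                         plate_extent = plate_extent,
                         supersample = supersample, margin = margin,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  gr <- gap_range(spec)
  if (!all(is.finite(gr)) || gr[1] < 0)
    stop("gap must be non-negative everywhere")
  spec
}

gap_at <- function(spec, theta, phi = 0) {
  if (is.null(spec$gap_function)) rep(spec$gap, length(theta))
  else spec$gap_function(theta, phi)
}

gap_range <- function(spec) {
  th <- seq(0, spec$cap_angle * pi / 180, length.out = 91)
  ph <- seq(0, 2 * pi, length.out = 25)
  range(outer(th, ph, function(a, b) gap_at(spec, a, b)))
}

max_gap <- function(spec) gap_range(spec)[2]

psf_sigma <- function(spec) {
  if (spec$psf_is_fwhm) spec$psf / (2 * sqrt(2 * log(2))) else spec$psf
}

# continuous (unblurred) density at world points
phantom_density <- function(spec, x, y, z) {
  d <- spec$densities
  if (spec$geometry == "ball_socket") {
    R <- spec$femoral_radius
    cx <- spec$cortex_thickness
    r <- sqrt(x^2 + y^2 + z^2)
    theta <- acos(pmin(pmax(ifelse(r > 0, z / r, 1), -1), 1))
    phi <- atan2(y, x)
    cap <- spec$cap_angle * pi / 180
    g <- gap_at(spec, theta, phi)
    val <- rep(d[["background"]], length(x))
    in_cap <- theta <= cap
    val[in_cap & r > R & r <= R + g] <- d[["joint_tissue"]]
    sel <- in_cap & r > R + g & r <= R + g + cx
    val[sel] <- d[["cortex"]]
    val[in_cap & r > R + g + cx] <- d[["far"]]
    val[r <= R] <- d[["cortex"]]
    val[r <= R - cx] <- d[["interior"]]
    val
  } else {
    cx <- spec$cortex_thickness
    g <- spec$gap
    ext <- spec$plate_extent
    slab_bottom <- -(cx + 6)
    val <- rep(d[["background"]], length(x))
    lat <- abs(x) <= ext & abs(y) <= ext
    val[lat & z > -cx & z <= 0] <- d[["cortex"]]
    val[lat & z > slab_bottom & z <= -cx] <- d[["interior"]]
    val[lat & z > 0 & z <= g] <- d[["joint_tissue"]]
    val[lat & z > g & z <= g + cx] <- d[["cortex"]]
    val[lat & z > g + cx & z <= g + cx + 4] <- d[["far"]]
    val
  }
}

phantom_inside_femur <- function(spec, x, y, z) {
  if (spec$geometry == "ball_socket") {
    sqrt(x^2 + y^2 + z^2) <= spec$femoral_radius
  } else {
    abs(x) <= spec$plate_extent & abs(y) <= spec$plate_extent &
      z <= 0 & z > -(spec$cortex_thickness + 6)
  }
}

phantom_extent <- function(spec) {
  m <- spec$margin
  if (spec$geometry == "ball_socket") {
    R <- spec$femoral_radius
    reach <- R + max_gap(spec) + spec$cortex_thickness
    list(lo = c(-reach - m, -reach - m, -R - m),
         hi = c(reach + m, reach + m, reach + m))
  } else {
    e <- spec$plate_extent
    cx <- spec$cortex_thickness
    list(lo = c(-e - m, -e - m, -(cx + 6) - m),
         hi = c(e + m, e + m, spec$gap + cx + 4 + m))
  }
}

#' Generate a phantom CT volume, femoral mask and joint-margin boundary
#'
#' Samples the continuous phantom geometry on a supersampled grid, convolves
#' with the anisotropic Gaussian PSF at that fine resolution, then integrates
#' over each voxel (partial volume) and adds seeded Gaussian noise — the
#' physical acquisition order, so the realised blur matches the closed-form
#' model closely.  Identical specs (including seed) produce bit-identical
#' volumes.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (blurred, noisy [image_volume]), `mask`
#'   (binary femoral-bone [image_volume]), `boundary` (closed polyline of
#'   world points on the femoral surface at the joint margin), `spec`.
#' @export
generate_volume <- function(spec) {
  ext <- phantom_extent(spec)
  sp <- spec$spacing
  n <- pmax(ceiling((ext$hi - ext$lo) / sp), 8)
  origin <- ext$lo + sp / 2
  idx <- lapply(1:3, function(a) origin[a] + sp[a] * (seq_len(n[a]) - 1))
  ss <- rep(spec$supersample, length.out = 3)
  if (any(ss %% 2 == 0)) stop("supersample factors must be odd")
  nf <- n * ss
  spf <- sp / ss
  originf <- ext$lo + spf / 2
  idxf <- lapply(1:3, function(a) originf[a] + spf[a] * (seq_len(nf[a]) - 1))
  sig <- psf_sigma(spec)
  # The composite kernel per axis is the Gaussian PSF convolved with the
  # voxel box, applied to the finely sampled geometry and evaluated at
  # coarse voxel centres only.  The z axis is streamed slab by slab so the
  # fine grid is never materialised in full.
  k3v <- composite_kernel(sig[3], sp[3], spf[3])
  k3m <- composite_kernel(0, sp[3], spf[3])
  r3v <- (length(k3v) - 1L) %/% 2L
  r3m <- (length(k3m) - 1L) %/% 2L
  xy_x <- rep(idxf[[1]], times = nf[2])
  xy_y <- rep(idxf[[2]], each = nf[1])
  nplane <- as.numeric(nf[1]) * nf[2]
  volz <- array(0, c(nf[1], nf[2], n[3]))
  maskz <- array(0, c(nf[1], nf[2], n[3]))
  off3 <- (ss[3] - 1L) %/% 2L
  dens_cache <- new.env(parent = emptyenv())
  mask_cache <- new.env(parent = emptyenv())
  plane <- function(cache, fz, fun) {
    key <- as.character(fz)
    v <- cache[[key]]
    if (is.null(v)) {
      zl <- idxf[[3]][fz + 1L]
      v <- fun(spec, xy_x, xy_y, rep(zl, nplane))
      cache[[key]] <- v
    }
    v
  }
  for (j in seq_len(n[3])) {
    centre <- off3 + (j - 1L) * ss[3]           # 0-based fine z index
    vacc <- numeric(nplane)
    macc <- numeric(nplane)
    for (tki in seq_along(k3v)) {
      fz <- min(max(centre + tki - 1L - r3v, 0L), nf[3] - 1L)
      vacc <- vacc + k3v[tki] * plane(dens_cache, fz, phantom_density)
      if (tki > r3v - r3m && tki <= r3v + r3m + 1L) {
        macc <- macc + k3m[tki - (r3v - r3m)] *
          plane(mask_cache, fz, function(...) as.numeric(phantom_inside_femur(...)))
      }
    }
    volz[, , j] <- vacc
    maskz[, , j] <- macc
    # evict planes that can no longer be needed
    done <- as.integer(ls(dens_cache)) < centre + ss[3] - r3v
    rm(list = ls(dens_cache)[done], envir = dens_cache)
    donem <- as.integer(ls(mask_cache)) < centre + ss[3] - r3m
    rm(list = ls(mask_cache)[donem], envir = mask_cache)
  }
  conv_xy <- function(values) {
    dims <- c(nf[1], nf[2], n[3])
    for (ax in 1:2) {
      k <- composite_kernel(sig[ax], sp[ax], spf[ax])
      values <- conv_axis_ds_cpp(as.numeric(values), dims, k, ax - 1L,
                                 ss[ax], (ss[ax] - 1L) %/% 2L)
      dims <- attr(values, "odim")
    }
    array(values, n)
  }
  conv_xy_box <- function(values) {
    dims <- c(nf[1], nf[2], n[3])
    for (ax in 1:2) {
      k <- composite_kernel(0, sp[ax], spf[ax])
      values <- conv_axis_ds_cpp(as.numeric(values), dims, k, ax - 1L,
                                 ss[ax], (ss[ax] - 1L) %/% 2L)
      dims <- attr(values, "odim")
    }
    array(values, n)
  }
  vol <- image_volume(conv_xy(volz), spacing = sp, origin = origin)
  mask <- image_volume(array(as.numeric(conv_xy_box(maskz) >= 0.5), n),
                       spacing = sp, origin = origin)
  rm(volz, maskz)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vol$data <- vol$data + array(rnorm(prod(n), sd = spec$noise_sd), n)
  }
  list(volume = vol, mask = mask, boundary = phantom_boundary(spec),
       spec = spec)
}

# Gaussian(sigma) x box(voxel) kernel sampled at the fine grid spacing;
# sigma of 0 reduces to the pure partial-volume box.
composite_kernel <- function(sigma, voxel, fine) {
  r <- max(1L, ceiling((4 * sigma + voxel / 2) / fine))
  u <- seq(-r, r) * fine
  s <- max(sigma, 1e-9)
  w <- pnorm((u + voxel / 2) / s) - pnorm((u - voxel / 2) / s)
  w / sum(w)
}

phantom_boundary <- function(spec, n_points = 72, theta = NULL) {
  if (spec$geometry == "ball_socket") {
    th <- theta %||% (spec$boundary_angle * pi / 180)
    phi <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
    R <- spec$femoral_radius
    if (length(th) == 1) th <- rep(th, length(phi))
    pts <- cbind(R * sin(th) * cos(phi), R * sin(th) * sin(phi),
                 R * cos(th))
  } else {
    e <- spec$plate_extent - 2
    s <- seq(-e, e, length.out = 12)
    pts <- rbind(cbind(s, -e, 0), cbind(e, s, 0),
                 cbind(rev(s), e, 0), cbind(-e, rev(s), 0))
    pts <- pts[!duplicated(pts), , drop = FALSE]
  }
  rbind(pts, pts[1, , drop = FALSE])
}

#' Analytic ground-truth joint space width on a patch
#'
#' The exact gap along each vertex direction from the phantom geometry.
#' Vertices must lie on the femoral outer surface to within `tolerance`;
#' vertices outside the acetabular cap get `NA` (no opposing bone).
#'
#' @param spec a [phantom_spec()].
#' @param patch a `joint_space_patch` (or [triangle_mesh]) on the phantom's
#'   femoral surface.
#' @param tolerance allowed |distance to surface| in mm (default 1).
#' @return numeric vector of per-vertex gap in mm.
#' @export
ground_truth_jsw <- function(spec, patch, tolerance = 1) {
  v <- (if (inherits(patch, "joint_space_patch")) patch$mesh else patch)$vertices
  if (spec$geometry == "ball_socket") {
    r <- sqrt(rowSums(v^2))
    if (max(abs(r - spec$femoral_radius)) > tolerance)
      stop("patch vertices are off the femoral surface by up to ",
           round(max(abs(r - spec$femoral_radius)), 2), " mm")
    theta <- acos(pmin(pmax(v[, 3] / r, -1), 1))
    phi <- atan2(v[, 2], v[, 1])
    g <- gap_at(spec, theta, phi)
    g[theta > spec$cap_angle * pi / 180] <- NA_real_
    g
  } else {
    if (max(abs(v[, 3])) > tolerance)
      stop("patch vertices are off the femoral plate surface")
    ifelse(abs(v[, 1]) <= spec$plate_extent & abs(v[, 2]) <= spec$plate_extent,
           spec$gap, NA_real_)
  }
}

#' Simulate two operators' joint-margin segmentations
#'
#' The second operator's boundary loop is the first perturbed along the
#' femoral surface by a smooth random angular displacement (low-order
#' Fourier series in loop parameter) of root-mean-square amplitude
#' `boundary_jitter` mm, reproducing inter-operator variability in joint
#' space margin definition.
#'
#' @param spec a [phantom_spec()] (ball_socket).
#' @param boundary_jitter RMS tangential displacement in mm (>= 0).
#' @param n_points loop points.
#' @return list with `op1`, `op2` closed boundary polylines.
#' @export
simulate_two_operators <- function(spec, boundary_jitter, n_points = 72) {
  stopifnot(boundary_jitter >= 0)
  op1 <- phantom_boundary(spec, n_points)
  if (boundary_jitter == 0) return(list(op1 = op1, op2 = op1))
  set.seed(spec$seed + 1L)
  phi <- seq(0, 2 * pi, length.out = n_points + 1)[-(n_points + 1)]
  coef <- rnorm(6)
  delta <- coef[1] * cos(phi) + coef[2] * sin(phi) +
    coef[3] * cos(2 * phi) + coef[4] * sin(2 * phi) +
    coef[5] * cos(3 * phi) + coef[6] * sin(3 * phi)
  delta <- delta / sqrt(mean(delta^2)) * boundary_jitter
  th2 <- spec$boundary_angle * pi / 180 + delta / spec$femoral_radius
  op2 <- phantom_boundary(spec, n_points, theta = th2)
  list(op1 = op1, op2 = op2)
}

#' Interior vertices of a patch
#'
#' Vertices further than `min_boundary_dist` from every boundary vertex —
#' used to restrict validation statistics to the patch interior, away from
#' margin effects.
#'
#' @param patch a `joint_space_patch`.
#' @param min_boundary_dist mm (default 3).
#' @return logical vector over patch vertices.
#' @export
interior_vertices <- function(patch, min_boundary_dist = 3) {
  v <- patch$mesh$vertices
  bnd <- patch$boundary
  if (length(bnd) == 0) bnd <- boundary_vertices(patch$mesh)
  if (length(bnd) == 0) return(rep(TRUE, nrow(v)))
  d <- nn_index_cpp(v, v[bnd, , drop = FALSE])$dist
  d > min_boundary_dist
}
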