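new_jsw_map <- function(patch, jsw, fit_error, femoral_offset, flags,
                        method = "jsm", y_peak = NA_real_,
                        config = jsm_config()) {
  structure(list(patch = patch, jsw = jsw, fit_error = fit_error,
                 femoral_offset = femoral_offset, flags = flags,
                 method = method, y_peak = y_peak, config = config),
            class = "jsw_map")
}

#' @export
print.jsw_map <- function(x, ...) {
  ok <- x$flags == "ok"
  cat("jsw_map (", x$method, "): ", length(x$jsw), " vertices, ",
      sum(ok), " ok\n", sep = "")
  if (any(!is.na(x$jsw)))
    cat(sprintf("  JSW median %.2f mm [%.2f, %.2f]\n",
                median(x$jsw, na.rm = TRUE), min(x$jsw, na.rm = TRUE),
                max(x$jsw, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a per-vertex joint space width map
#'
#' @param x a `jsw_map`.
#' @param ... unused.
#' @return A tibble with one row per patch vertex: `vertex`, `jsw_mm`,
#'   `fit_error_hu`, `femoral_offset_mm`, `flag`.
#' @export
tidy.jsw_map <- function(x, ...) {
  tibble::tibble(vertex = seq_along(x$jsw), jsw_mm = x$jsw,
                 fit_error_hu = x$fit_error,
                 femoral_offset_mm = x$femoral_offset, flag = x$flags)
}

#' @rdname tidy.jsw_map
#' @export
glance.jsw_map <- function(x, ...) {
  ok <- x$flags == "ok"
  tibble::tibble(n_vertices = length(x$jsw), n_ok = sum(ok),
                 ok_frac = mean(ok),
                 jsw_median_mm = median(x$jsw, na.rm = TRUE),
                 jsw_mean_mm = mean(x$jsw, na.rm = TRUE),
                 fit_error_median_hu = median(x$fit_error, na.rm = TRUE),
                 y_peak_hu = x$y_peak, method = x$method)
}

#' Generic tidiers
#'
#' `tidy()` and `glance()` generics (as in the broom package) for jsmap
#' result objects.
#' @param x an object.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Measure joint space width across a patch
#'
#' The core measurement: at every patch vertex a line profile is sampled
#' along the outward normal, the blurred double-peak model is fitted with
#' the fixed peak density constraint, and the deconvolved edge positions
#' give the joint space width, the femoral surface offset (displacement of
#' the fitted femoral outer surface from the patch vertex) and the fit
#' residual.  All steps are automatic.
#'
#' @param patch a `joint_space_patch`.
#' @param volume the CT [image_volume].
#' @param config a [jsm_config()].
#' @param y_peak fixed peak cortical density (HU); estimated with
#'   [estimate_peak_density()] on `bone_mesh` (or the patch mesh itself)
#'   when omitted.
#' @param bone_mesh optional whole-bone [triangle_mesh] for the peak density
#'   estimate.
#' @return A `jsw_map` with per-vertex `jsw`, `fit_error`,
#'   `femoral_offset` and `flags`.
#' @export
measure_patch <- function(patch, volume, config = jsm_config(), y_peak = NULL,
                          bone_mesh = NULL) {
  nv <- nrow(patch$mesh$vertices)
  if (is.null(y_peak)) {
    y_peak <- estimate_peak_density(volume, bone_mesh %||% patch$mesh, config)
  }
  jsw <- err <- off <- rep(NA_real_, nv)
  flags <- character(nv)
  for (i in seq_len(nv)) {
    prof <- tryCatch(
      sample_profile(volume, patch$mesh$vertices[i, ], patch$mesh$normals[i, ],
                     t_min = config$t_min, t_max = config$t_max,
                     step = config$step, interp = config$interp),
      error = function(e) NULL)
    if (is.null(prof)) {
      flags[i] <- "out_of_bounds"
      next
    }
    fit <- fit_double_peak(prof, y_peak = y_peak, y_js = config$y_js,
                           config = config)
    flags[i] <- fit$status
    err[i] <- fit$rms_residual
    if (!is.null(fit$model)) off[i] <- fit$model$x1
    if (fit$status == "ok") jsw[i] <- fit$jsw
  }
  if (all(flags == "out_of_bounds"))
    stop("patch lies entirely outside the volume")
  if (mean(flags == "fit_failed") > 0.5)
    stop("measurement failed: ", sum(flags == "fit_failed"), " of ", nv,
         " vertex fits did not converge")
  new_jsw_map(patch, jsw = jsw, fit_error = err, femoral_offset = off,
              flags = flags, method = "jsm", y_peak = y_peak, config = config)
}

#' Steep-gradient outlier removal
#'
#' Flattens false peaks in the measured joint surface: a vertex whose
#' femoral surface offset deviates from the median of its 1-ring neighbours
#' by more than `threshold` is masked and its values refilled from
#' neighbours.  Using the ring median (not mean) keeps pairs of adjacent
#' spikes detectable.  At most `max_frac` of the ok vertices are altered
#' (worst deviations first), so smooth inputs pass through unchanged.
#'
#' @param map a `jsw_map`.
#' @param threshold deviation threshold in mm (default from the map config).
#' @param max_frac cap on the altered fraction of ok vertices.
#' @return The filtered `jsw_map`.
#' @export
remove_outliers <- function(map, threshold = NULL, max_frac = NULL) {
  threshold <- threshold %||% map$config$gradient_threshold
  max_frac <- max_frac %||% map$config$outlier_max_frac
  ok <- map$flags == "ok"
  if (sum(ok) < 10) stop("need at least 10 ok vertices")
  adj <- vertex_adjacency(map$patch$mesh)
  dev <- rep(NA_real_, length(ok))
  for (i in which(ok)) {
    nb <- adj[[i]]
    nb_off <- map$femoral_offset[nb]
    nb_off <- nb_off[is.finite(nb_off)]
    if (length(nb_off) < 2) next
    dev[i] <- abs(map$femoral_offset[i] - median(nb_off))
  }
  cand <- which(ok & !is.na(dev) & dev > threshold)
  cap <- floor(max_frac * sum(ok))
  if (length(cand) > cap) cand <- cand[order(dev[cand], decreasing = TRUE)][seq_len(cap)]
  if (length(cand) == sum(ok)) stop("outlier removal would mask every vertex")
  map$jsw[cand] <- NA_real_
  map$femoral_offset[cand] <- NA_real_
  map$flags[cand] <- "outlier"
  map <- fill_missing(map, refill = cand)
  attr(map, "n_removed") <- length(cand)
  map
}

# Fill missing jsw/offset values from neighbour means, iterating until no
# fillable vertex remains.  Refilled outlier vertices are marked "refilled".
fill_missing <- function(map, refill = integer(0)) {
  adj <- vertex_adjacency(map$patch$mesh)
  for (pass in 1:50) {
    missing <- which(is.na(map$jsw))
    if (length(missing) == 0) break
    filled_any <- FALSE
    new_jsw <- map$jsw
    new_off <- map$femoral_offset
    for (i in missing) {
      nb <- adj[[i]]
      v <- map$jsw[nb]
      if (!any(is.finite(v))) next
      new_jsw[i] <- mean(v, na.rm = TRUE)
      o <- map$femoral_offset[nb]
      new_off[i] <- if (any(is.finite(o))) mean(o, na.rm = TRUE) else 0
      filled_any <- TRUE
    }
    map$jsw <- new_jsw
    map$femoral_offset <- new_off
    if (!filled_any) break
  }
  if (length(refill)) map$flags[refill] <- "refilled"
  map
}

#' Error-based smoothing of a joint space width map
#'
#' Graph-Laplacian smoothing in which each vertex moves towards the plain
#' mean of its neighbours with a mobility that increases with its own fit
#' error: the per-vertex reliability weight is
#' `w = 1 / (1 + (fit_error / median fit_error)^2)` and the per-iteration
#' step is `step * (1 - w)`, so accurately fitted vertices barely move while
#' poorly fitted ones are pulled most of the way to their neighbourhood
#' consensus.  The neighbour average is unweighted on purpose: weighting it
#' by reliability biases measurements wherever fit error correlates with the
#' signal (e.g. along a narrowing joint space).  Missing vertices are first
#' interpolated from neighbours.
#'
#' @param map a `jsw_map` with `fit_error` populated.
#' @param iterations,step smoothing iterations and step size (defaults from
#'   the map config: 10 iterations, step 0.5).
#' @return The smoothed `jsw_map`.
#' @export
smooth_map <- function(map, iterations = NULL, step = NULL) {
  iterations <- iterations %||% map$config$smooth_iterations
  step <- step %||% map$config$smooth_step
  map <- fill_missing(map)
  adj <- vertex_adjacency(map$patch$mesh)
  err <- map$fit_error
  med <- median(err[is.finite(err)], na.rm = TRUE)
  if (!is.finite(med) || med <= 0) med <- 1
  w <- 1 / (1 + (err / med)^2)
  w[!is.finite(w)] <- 0.5
  v <- map$jsw
  for (it in seq_len(iterations)) {
    nbr_mean <- v
    for (i in seq_along(v)) {
      nb <- adj[[i]]
      if (length(nb) == 0 || !is.finite(v[i])) next
      vn <- v[nb]
      fin <- is.finite(vn)
      if (!any(fin)) next
      nbr_mean[i] <- mean(vn[fin])
    }
    mob <- step * (1 - w)
    v <- v + mob * (nbr_mean - v)
  }
  map$jsw <- v
  map
}

#' Build the femoral and acetabular joint surface meshes
#'
#' The femoral joint surface is the patch displaced along its normals by the
#' fitted femoral offsets; the acetabular surface is the femoral surface
#' displaced further by the joint space width.  Both share the patch
#' triangulation, and together they delimit the joint space volume.
#'
#' @param map a smoothed `jsw_map` with at least 80% ok vertices.
#' @return list with `femoral` and `acetabular` [triangle_mesh] objects.
#' @export
build_joint_surfaces <- function(map) {
  usable <- map$flags %in% c("ok", "refilled")
  if (mean(usable) < 0.8)
    stop("need at least 80% usable vertices (have ",
         round(100 * mean(usable)), "%)")
  map <- fill_missing(map)
  mesh <- map$patch$mesh
  off <- ifelse(is.finite(map$femoral_offset), map$femoral_offset, 0)
  jsw <- ifelse(is.finite(map$jsw), map$jsw, 0)
  fem_v <- mesh$vertices + off * mesh$normals
  ace_v <- fem_v + jsw * mesh$normals
  fem <- triangle_mesh(fem_v, mesh$triangles)
  fem$normals <- orient_like(fem, mesh$normals)
  ace <- triangle_mesh(ace_v, mesh$triangles)
  ace$normals <- orient_like(ace, mesh$normals)
  list(femoral = fem, acetabular = ace)
}

#' Plot a joint space width map
#'
#' Vertices are laid out by their two principal tangential directions and
#' coloured by joint space width.
#'
#' @param object a `jsw_map`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot jsw_map
#' @export
autoplot.jsw_map <- function(object, ...) {
  v <- object$patch$mesh$vertices
  pc <- stats::prcomp(v, rank. = 2)
  df <- tibble::tibble(u = pc$x[, 1], w = pc$x[, 2], jsw = object$jsw)
  ggplot2::ggplot(df, ggplot2::aes(x = u, y = w, colour = jsw)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c(name = "JSW (mm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "patch axis 1 (mm)", y = "patch axis 2 (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
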