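#' Trim values to their central 95% range
#'
#' Values outside the 2.5th-97.5th percentile interval are set to missing —
#' used to strip noise from the extremes of reference (high-resolution)
#' data before computing agreement.  Percentiles use the piecewise-linear
#' type-5 definition and values equal to either percentile are retained
#' (only strictly outside values are removed), so the operation is
#' idempotent.
#'
#' An already-trimmed vector (recognised by its recorded trim bounds) is
#' returned unchanged, so the operation is idempotent.
#'
#' @param values numeric vector (>= 40 finite values).
#' @return `values` with the extremes replaced by `NA`; the applied bounds
#'   are recorded in `attr(, "trim_bounds")`.
#' @export
trim_95 <- function(values) {
  if (!is.null(attr(values, "trim_bounds"))) return(values)
  fin <- is.finite(values)
  if (sum(fin) < 40) stop("need at least 40 finite values to trim")
  q <- quantile(values[fin], c(0.025, 0.975), type = 5, names = FALSE)
  out <- values
  out[fin & (values < q[1] | values > q[2])] <- NA_real_
  attr(out, "trim_bounds") <- q
  out
}

#' Accuracy and precision between two matched maps
#'
#' Accuracy (bias) is the mean of A minus B over vertices measured in both;
#' precision is the sample standard deviation of those differences.
#'
#' @param map_a,map_b numeric vectors of per-vertex values on the same
#'   surface (e.g. clinical-CT and high-resolution JSW), or `jsw_map`
#'   objects.
#' @return named list with `bias`, `precision` (mm) and `n`.
#' @export
accuracy_precision <- function(map_a, map_b) {
  a <- map_values(map_a)
  b <- map_values(map_b)
  if (length(a) != length(b)) stop("maps must share a surface (equal lengths)")
  d <- a - b
  d <- d[is.finite(d)]
  if (length(d) == 0) stop("no matched vertices with values in both maps")
  list(bias = mean(d), precision = if (length(d) > 1) sd(d) else 0,
       n = length(d))
}

map_values <- function(x) if (inherits(x, "jsw_map")) x$jsw else as.numeric(x)

#' Bland-Altman agreement between two operators
#'
#' Bias is the mean of operator-1 minus operator-2 differences; the 95%
#' limits of agreement are bias +/- 1.96 times the SD of the differences.
#'
#' @param op1,op2 numeric vectors of paired measurements (or `jsw_map`s).
#' @return A `bland_altman` object: list with `bias`, `loa` (1.96 x SD),
#'   `n`, and a tibble `data` of per-pair means and differences for
#'   plotting.
#' @export
bland_altman <- function(op1, op2) {
  a <- map_values(op1)
  b <- map_values(op2)
  if (length(a) != length(b)) stop("operators must supply paired values")
  fin <- is.finite(a) & is.finite(b)
  a <- a[fin]; b <- b[fin]
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  structure(list(bias = mean(d), loa = 1.96 * sd(d), n = length(d),
                 data = tibble::tibble(mean = (a + b) / 2, diff = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, limits of agreement +/- %.4f (n = %d)\n",
              x$bias, x$loa, x$n))
  invisible(x)
}

#' @rdname tidy
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, loa = x$loa, n = x$n)
}

#' @rdname bland_altman
#' @param object a `bland_altman` object.
#' @param ... unused.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = mean, y = diff)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "red") +
    ggplot2::geom_hline(yintercept = object$bias + c(-1, 1) * object$loa,
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = "pair mean (mm)", y = "operator difference (mm)") +
    ggplot2::theme_minimal()
}

#' Root-mean-square coefficient of variation
#'
#' Each pair contributes CV = SD / mean (sample SD of the two values,
#' |a - b| / sqrt(2)); RMSCV is 100 times the square root of the mean of the
#' squared CVs, in percent.
#'
#' @param pairs 2-column matrix (or data frame) of paired measurements.
#' @return RMSCV in percent.
#' @export
rmscv <- function(pairs) {
  p <- as.matrix(pairs)
  if (ncol(p) != 2) stop("pairs must have two columns")
  fin <- is.finite(p[, 1]) & is.finite(p[, 2])
  p <- p[fin, , drop = FALSE]
  m <- rowMeans(p)
  if (any(m <= 0)) stop("CV undefined: a pair mean is zero or negative")
  cv <- (abs(p[, 1] - p[, 2]) / sqrt(2)) / m
  100 * sqrt(mean(cv^2))
}

#' Full agreement report between two measurement sets
#'
#' @param map_a,map_b per-vertex values (or `jsw_map`s) on a shared surface.
#' @param trim apply [trim_95()] to `map_b` (the reference) first.
#' @return An `agreement_report`: `n_pairs`, `bias`, `precision`, `loa`,
#'   `rmscv`.
#' @export
agreement_report <- function(map_a, map_b, trim = FALSE) {
  a <- map_values(map_a)
  b <- map_values(map_b)
  if (trim) b <- trim_95(b)
  ap <- accuracy_precision(a, b)
  fin <- is.finite(a) & is.finite(b)
  rc <- if (all(a[fin] + b[fin] > 0)) rmscv(cbind(a[fin], b[fin])) else NA_real_
  structure(list(n_pairs = ap$n, bias = ap$bias, precision = ap$precision,
                 loa = 1.96 * ap$precision, rmscv = rc),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0("agreement_report: n = %d, bias %.3f mm, precision ",
                     "%.3f mm, LoA +/- %.3f mm, RMSCV %.2f%%\n"),
              x$n_pairs, x$bias, x$precision, x$loa, x$rmscv))
  invisible(x)
}

#' @rdname tidy
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, bias = x$bias, precision = x$precision,
                 loa = x$loa, rmscv = x$rmscv)
}

#' Per-vertex agreement maps across subjects
#'
#' Applies the global agreement formulas vertex by vertex across a cohort
#' whose maps have all been transferred onto one average surface: bias and
#' precision of A minus B, limits of agreement, and RMSCV.  Vertices with
#' fewer than `min_subjects` contributing subjects are masked.
#'
#' @param maps_a,maps_b lists of per-vertex value vectors (one per subject),
#'   all on the same average surface.
#' @param min_subjects minimum subjects per vertex (default 3).
#' @return A tibble with one row per vertex: `vertex`, `n`, `bias`,
#'   `precision`, `loa`, `rmscv`.
#' @export
per_vertex_maps <- function(maps_a, maps_b, min_subjects = 3) {
  A <- do.call(cbind, lapply(maps_a, map_values))
  B <- do.call(cbind, lapply(maps_b, map_values))
  if (!all(dim(A) == dim(B))) stop("mismatched surfaces across collections")
  D <- A - B
  n <- rowSums(is.finite(D))
  bias <- rowMeans(D, na.rm = TRUE)
  prec <- apply(D, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) > 1) sd(r) else NA_real_
  })
  rc <- vapply(seq_len(nrow(A)), function(i) {
    a <- A[i, ]; b <- B[i, ]
    fin <- is.finite(a) & is.finite(b)
    if (!any(fin) || any(a[fin] + b[fin] <= 0)) return(NA_real_)
    rmscv(cbind(a[fin], b[fin]))
  }, numeric(1))
  mask <- n < min_subjects
  bias[mask] <- prec[mask] <- rc[mask] <- NA_real_
  tibble::tibble(vertex = seq_len(nrow(A)), n = n, bias = bias,
                 precision = prec, loa = 1.96 * prec, rmscv = rc)
}
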