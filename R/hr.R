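#' Adaptive half-maximum joint space measurement (high-resolution reference)
#'
#' On high-resolution data the image blur is small enough that a simple
#' adaptive threshold locates the outer cortical surfaces directly.  The
#' local density peak closest to the patch vertex (`t = 0`) is taken as the
#' femoral joint surface; its half-maximum value — half the peak amplitude
#' above the joint tissue density — is the threshold whose outward crossing
#' (linear sub-sample interpolation) is the femoral outer surface.  A search
#' then continues outwards for the next cortical peak above that threshold;
#' its own half-maximum crossing, approached from the joint space side, is
#' the acetabular outer surface.  Joint space width is the distance between
#' the two crossings.  For an isolated blurred step the half-amplitude
#' crossing coincides with the true edge, which is what makes this accurate
#' when the point spread function is much narrower than the structures.
#'
#' @param profile a `line_profile` (step no coarser than `min_step`).
#' @param y_js joint tissue density (HU, default 35) used as the baseline for
#'   peak amplitude.
#' @param prominence minimum peak height above `y_js` (HU, default 150).
#' @param min_step maximum admissible profile step (mm, default 0.1: the
#'   high-resolution regime).
#' @return A `threshold_measurement`: list with `femoral_edge`,
#'   `acetabular_edge`, `jsw` (mm), `femoral_peak`, `acetabular_peak` (HU)
#'   and `status` (`"ok"`, `"no_second_peak"` or `"failed"`).
#' @export
measure_half_max <- function(profile, y_js = 35, prominence = 150,
                             min_step = 0.1) {
  t <- profile$t
  v <- profile$values
  if (length(t) > 1 && (t[2] - t[1]) > min_step + 1e-9)
    stop("profile step ", t[2] - t[1], " mm is too coarse for the ",
         "half-maximum measurement (need <= ", min_step, " mm)")
  out <- function(status, fe = NA_real_, ae = NA_real_, fp = NA_real_,
                  ap = NA_real_) {
    structure(list(femoral_edge = fe, acetabular_edge = ae,
                   jsw = if (status == "ok") ae - fe else NA_real_,
                   femoral_peak = fp, acetabular_peak = ap, status = status),
              class = "threshold_measurement")
  }
  vf <- moving_median3(v)
  pk <- local_maxima(vf)
  pk <- pk[vf[pk] >= y_js + prominence]
  if (length(pk) == 0) return(out("failed"))
  fem_i <- pk[which.min(abs(t[pk]))]
  fem_peak <- vf[fem_i]
  thr_f <- (fem_peak + y_js) / 2
  fe <- crossing_after(t, vf, fem_i, thr_f, direction = "down")
  if (is.na(fe)) return(out("failed", fp = fem_peak))
  # outward search: next peak above the femoral threshold beyond the edge
  cand <- pk[t[pk] > fe & pk != fem_i & vf[pk] >= thr_f]
  if (length(cand) == 0) return(out("no_second_peak", fe = fe, fp = fem_peak))
  ace_i <- cand[1]
  ace_peak <- vf[ace_i]
  thr_a <- (ace_peak + y_js) / 2
  ae <- crossing_before(t, vf, ace_i, thr_a, limit_t = fe)
  if (is.na(ae) || ae <= fe) return(out("no_second_peak", fe = fe, fp = fem_peak))
  out("ok", fe = fe, ae = ae, fp = fem_peak, ap = ace_peak)
}

#' @export
print.threshold_measurement <- function(x, ...) {
  cat("threshold_measurement:", x$status)
  if (!is.na(x$jsw)) cat(sprintf(", JSW = %.3f mm", x$jsw))
  cat("\n")
  invisible(x)
}

# 3-sample moving median (ends passed through).
moving_median3 <- function(v) {
  n <- length(v)
  if (n < 3) return(v)
  a <- v[1:(n - 2)]
  b <- v[2:(n - 1)]
  c <- v[3:n]
  out <- v
  out[2:(n - 1)] <- pmax(pmin(a, b), pmin(pmax(a, b), c))
  out
}

# indices of strict local maxima (plateaus take their first sample)
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  d <- diff(v)
  s <- sign(d)
  # propagate the sign across zero-slope plateaus
  for (i in seq_len(n - 1)[-1]) if (s[i] == 0) s[i] <- s[i - 1]
  which(diff(s) < 0) + 1L
}

# first threshold crossing after index i (moving to larger t, downward slope)
crossing_after <- function(t, v, i, thr, direction = "down") {
  n <- length(v)
  for (j in i:(n - 1)) {
    if (v[j] >= thr && v[j + 1] < thr) {
      f <- (thr - v[j]) / (v[j + 1] - v[j])
      return(t[j] + f * (t[j + 1] - t[j]))
    }
  }
  NA_real_
}

# last upward crossing before index i (approaching the peak from smaller t),
# not earlier than limit_t
crossing_before <- function(t, v, i, thr, limit_t = -Inf) {
  for (j in seq(i - 1, 1)) {
    if (t[j] < limit_t) break
    if (v[j] < thr && v[j + 1] >= thr) {
      f <- (thr - v[j]) / (v[j + 1] - v[j])
      return(t[j] + f * (t[j + 1] - t[j]))
    }
  }
  NA_real_
}

#' Measure a joint space patch with the adaptive half-maximum method
#'
#' Applies [measure_half_max()] to the profile at every patch vertex.  No
#' smoothing is applied to the result; failed vertices stay missing.
#'
#' @param patch a `joint_space_patch`.
#' @param volume the high-resolution [image_volume].
#' @param config a [jsm_config()] (profile geometry); the profile step should
#'   be at or below 0.1 mm.
#' @param y_js,prominence see [measure_half_max()].
#' @return A `jsw_map` (see [measure_patch()]); `femoral_offset` holds the
#'   femoral edge position and `fit_error` is `NA` (no model fit involved).
#' @export
measure_patch_hr <- function(patch, volume, config = jsm_config(),
                             y_js = 35, prominence = 150) {
  nv <- nrow(patch$mesh$vertices)
  jsw <- off <- rep(NA_real_, nv)
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
    m <- measure_half_max(prof, y_js = y_js, prominence = prominence,
                          min_step = config$step + 1e-9)
    flags[i] <- if (m$status == "ok") "ok" else m$status
    if (m$status == "ok") {
      jsw[i] <- m$jsw
      off[i] <- m$femoral_edge
    } else if (!is.na(m$femoral_edge)) {
      off[i] <- m$femoral_edge
    }
  }
  new_jsw_map(patch, jsw = jsw, fit_error = rep(NA_real_, nv),
              femoral_offset = off, flags = flags, method = "hr_half_max")
}

#' Filter positional and extreme-value outliers from a half-maximum map
#'
#' Replaces the manual review step: vertices whose femoral edge sits further
#' than `positional_limit` from the patch surface, or whose joint space
#' width falls outside `value_limits`, are set to missing.  Remaining values
#' are untouched (no smoothing is ever applied to the high-resolution data).
#' The filter is idempotent.
#'
#' @param map a `jsw_map` from [measure_patch_hr()].
#' @param positional_limit max |femoral edge| in mm (default 2).
#' @param value_limits admissible JSW range in mm (default `c(0.2, 10)`).
#' @return The filtered `jsw_map`; the fraction removed is stored in
#'   `attr(, "removed_frac")`.
#' @export
filter_hr_outliers <- function(map, positional_limit = 2,
                               value_limits = c(0.2, 10)) {
  ok <- map$flags == "ok"
  bad <- ok & (abs(map$femoral_offset) > positional_limit |
               map$jsw < value_limits[1] | map$jsw > value_limits[2])
  bad[is.na(bad)] <- FALSE
  map$jsw[bad] <- NA_real_
  map$femoral_offset[bad] <- NA_real_
  map$flags[bad] <- "filtered"
  attr(map, "removed_frac") <- if (any(ok)) sum(bad) / sum(ok) else 0
  map
}
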