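#' Measurement configuration
#'
#' Collects the tunable parameters of the joint space measurement pipeline.
#' All distances are mm, all densities HU.
#'
#' @param t_min,t_max profile sampling extent about each vertex (mm).  The
#'   inward extent covers the femoral cortex, the outward extent reaches
#'   beyond the largest expected gap plus acetabular cortex.
#' @param step profile sampling step (mm).
#' @param interp profile interpolation: `"cubic"` or `"linear"`.
#' @param y_js joint space tissue density (HU); cartilage is taken as 35 HU.
#' @param sigma_bounds admissible Gaussian blur SD range for the fit (mm).
#' @param search_depth opposing-bone projection depth (mm).
#' @param offset_limit plausibility limit on the fitted femoral surface
#'   displacement from the patch vertex (mm).  The default 2.5 leaves a
#'   guard band beyond the +/-2 mm segmentation tolerance so that fits on a
#'   surface at the tolerance edge are not clipped by their own noise.
#' @param gradient_threshold steep-gradient outlier threshold: maximum
#'   deviation of a vertex's femoral offset from its 1-ring median (mm).
#' @param outlier_max_frac upper bound on the fraction of ok vertices the
#'   outlier filter may alter.
#' @param smooth_iterations,smooth_step error-based smoothing iterations and
#'   step size.
#' @param peak_sample maximum number of mesh vertices used for peak cortical
#'   density estimation.
#' @param min_peak_amplitude minimum fitted cortical amplitude above
#'   surrounding tissue for a per-vertex peak-density fit to count (HU).
#' @param seed RNG seed used for vertex subsampling.
#' @return A list of class `jsm_config`.
#' @export
jsm_config <- function(t_min = -6, t_max = 10, step = 0.1,
                       interp = c("cubic", "linear"), y_js = 35,
                       sigma_bounds = c(0.1, 3.0), search_depth = 5,
                       offset_limit = 2.5, gradient_threshold = 1.0,
                       outlier_max_frac = 0.1, smooth_iterations = 10,
                       smooth_step = 0.5, peak_sample = 1000,
                       min_peak_amplitude = 150, seed = 1L) {
  interp <- match.arg(interp)
  structure(list(t_min = t_min, t_max = t_max, step = step, interp = interp,
                 y_js = y_js, sigma_bounds = sigma_bounds,
                 search_depth = search_depth, offset_limit = offset_limit,
                 gradient_threshold = gradient_threshold,
                 outlier_max_frac = outlier_max_frac,
                 smooth_iterations = smooth_iterations,
                 smooth_step = smooth_step, peak_sample = peak_sample,
                 min_peak_amplitude = min_peak_amplitude, seed = seed),
            class = "jsm_config")
}

#' Read a measurement configuration from a JSON file
#' @param path JSON file with any subset of [jsm_config()] fields.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(jsm_config, vals)
}
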