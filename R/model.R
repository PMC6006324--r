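#' Double-peak cortical density model
#'
#' The density along a ray crossing a joint is modelled as a piecewise
#' constant five-level profile: femoral interior (`y0`), femoral cortex
#' (`y_peak`), joint space tissue (`y_js`, fixed at 35 HU for cartilage),
#' acetabular cortex (`y_peak` again), and far-side tissue (`y3`), with edges
#' at `x0 < x1 < x2 < x3` (mm along the profile).  The imaging system blur is
#' a Gaussian point spread function of standard deviation `sigma`, so the
#' observed profile is the convolution of the step profile with that
#' Gaussian — a sum of Gaussian-CDF step terms in closed form.  Joint space
#' width is `x2 - x1`, the distance between the two outer (articular-facing)
#' bone surfaces.
#'
#' @param x0,x1,x2,x3 edge positions in mm (femoral endosteal, femoral outer,
#'   acetabular outer, acetabular endosteal).
#' @param y0 femoral interior density (HU).
#' @param y_peak cortical peak density (HU); fixed globally during fitting.
#' @param y_js joint space tissue density (HU, default 35).
#' @param y3 far-side density (HU).
#' @param sigma Gaussian blur SD in mm.
#' @return A `double_peak_model` list.
#' @export
double_peak_model <- function(x0, x1, x2, x3, y0, y_peak, y_js = 35, y3,
                              sigma) {
  if (!(x0 < x1 && x1 <= x2 && x2 < x3)) stop("edges must satisfy x0 < x1 <= x2 < x3")
  if (sigma < 0) stop("sigma must be non-negative")
  if (y_peak <= y_js) stop("y_peak must exceed y_js")
  structure(list(x0 = x0, x1 = x1, x2 = x2, x3 = x3, y0 = y0, y_peak = y_peak,
                 y_js = y_js, y3 = y3, sigma = sigma),
            class = "double_peak_model")
}

# Gaussian-blurred step: 0 below, 1 above the edge, blurred with SD sigma.
blurred_step <- function(t, edge, sigma) {
  if (sigma <= 1e-12) return(as.numeric(t >= edge))
  pnorm((t - edge) / sigma)
}

#' Evaluate the blurred double-peak model
#'
#' @param model a [double_peak_model] (or plain list with the same fields).
#' @param t sample positions in mm.
#' @return HU values at `t`.
#' @export
model_profile <- function(model, t) {
  m <- model
  m$y0 +
    (m$y_peak - m$y0) * blurred_step(t, m$x0, m$sigma) +
    (m$y_js - m$y_peak) * blurred_step(t, m$x1, m$sigma) +
    (m$y_peak - m$y_js) * blurred_step(t, m$x2, m$sigma) +
    (m$y3 - m$y_peak) * blurred_step(t, m$x3, m$sigma)
}

# Single-cortex variant: y_in | y_c | y_out with edges xa < xb.
single_cortex_profile <- function(t, xa, xb, y_in, y_c, y_out, sigma) {
  y_in +
    (y_c - y_in) * blurred_step(t, xa, sigma) +
    (y_out - y_c) * blurred_step(t, xb, sigma)
}
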