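# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# analytic line profile from a double-peak (or compatible) model
analytic_profile <- function(model, t_min = -6, t_max = 10, step = 0.1) {
  t <- seq(t_min, t_max, by = step)
  structure(list(t = t, values = model_profile(model, t),
                 origin = c(0, 0, 0), direction = c(0, 0, 1),
                 oob = rep(FALSE, length(t))),
            class = "line_profile")
}

profile_from_values <- function(t, values) {
  structure(list(t = t, values = values, origin = c(0, 0, 0),
                 direction = c(0, 0, 1), oob = rep(FALSE, length(t))),
            class = "line_profile")
}

# solid ball mask, radius 10 mm, isotropic 0.5 mm voxels
sphere_mask <- function() fixture("sphere_mask", function() {
  sp <- c(0.5, 0.5, 0.5)
  n <- c(49, 49, 49)
  orig <- c(-12, -12, -12)
  ax <- lapply(1:3, function(a) orig[a] + sp[a] * (0:(n[a] - 1)))
  x <- rep(ax[[1]], times = n[2] * n[3])
  y <- rep(rep(ax[[2]], each = n[1]), times = n[3])
  z <- rep(ax[[3]], each = n[1] * n[2])
  mask <- array(as.numeric(sqrt(x^2 + y^2 + z^2) <= 10), n)
  image_volume(mask, spacing = sp, origin = orig)
})

sphere_mesh <- function() fixture("sphere_mesh", function() {
  mesh_from_mask(sphere_mask())
})

hemisphere_patch <- function() fixture("hemisphere_patch", function() {
  phi <- seq(0, 2 * pi, length.out = 73)
  loop <- cbind(10 * cos(phi), 10 * sin(phi), 0)
  cut_patch(sphere_mesh(), loop, seed = c(0, 0, 10))
})

# clinical-regime ball-and-socket phantom whose gap rises smoothly from
# 1.5 mm at the pole to 4.5 mm, covering the validated range with patch
# area roughly proportional to each gap band
clinical_gap_fun <- function(theta, phi) {
  pmin(1.5 + 3.0 * (1 - cos(theta)) / (1 - cos(45 * pi / 180)), 4.5)
}

clinical_spec <- function() {
  phantom_spec("ball_socket", gap_function = clinical_gap_fun, seed = 7L)
}

clinical_phantom <- function() fixture("clinical_phantom", function() {
  spec <- clinical_spec()
  ph <- generate_volume(spec)
  mesh <- mesh_from_mask(ph$mask)
  patch <- retriangulate(cut_patch(mesh, ph$boundary, seed = c(0, 0, 20)), 900)
  y_peak <- estimate_peak_density(ph$volume, mesh)
  list(spec = spec, ph = ph, mesh = mesh, patch = patch, y_peak = y_peak,
       gt = ground_truth_jsw(spec, patch),
       interior = interior_vertices(patch, 3))
})

# the measured (raw) map on the clinical phantom, shared across tests
clinical_map <- function() fixture("clinical_map", function() {
  cp <- clinical_phantom()
  measure_patch(cp$patch, cp$ph$volume, y_peak = cp$y_peak)
})

# small isotropic ball phantom for peak-density estimation tests
shell_phantom <- function(sigma) {
  spec <- phantom_spec("ball_socket", femoral_radius = 10,
                       cortex_thickness = 2, gap = 3,
                       psf = rep(sigma, 3), psf_is_fwhm = FALSE,
                       noise_sd = 0, spacing = c(0.5, 0.5, 0.5),
                       margin = 4, seed = 2L)
  generate_volume(spec)
}

shell_mesh <- function() fixture("shell_mesh", function() {
  mesh_from_mask(shell_phantom(0.8)$mask)
})

# moderate open patch with asymmetric bumps (breaks rotational symmetry)
# for surface registration tests
bumpy_patch_mesh <- function() fixture("bumpy_patch_mesh", function() {
  spec <- phantom_spec("ball_socket", femoral_radius = 15, noise_sd = 0,
                       spacing = c(0.7, 0.7, 0.7), margin = 3, seed = 4L)
  ph <- generate_volume(spec)
  mesh <- mesh_from_mask(ph$mask)
  patch <- retriangulate(cut_patch(mesh, ph$boundary, seed = c(0, 0, 15)), 700)
  v <- patch$mesh$vertices
  r <- sqrt(rowSums(v^2))
  th <- acos(pmin(pmax(v[, 3] / r, -1), 1))
  phi <- atan2(v[, 2], v[, 1])
  bump <- 1 + 0.05 * (sin(3 * phi) + 0.8 * sin(phi + 1) +
                        0.6 * cos(2 * phi - 0.5)) * sin(th * 2.2)
  triangle_mesh(v * bump, patch$triangles %||% patch$mesh$triangles)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
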