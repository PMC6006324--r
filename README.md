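# jsmap — 3D joint space mapping from clinical CT

Joint diseases such as osteoarthritis are monitored through *joint space
width* (JSW): the distance between the opposing outer cortical bone
surfaces of a joint. At clinical CT resolution that distance is often
narrower than the scanner's point spread function (PSF), so naive edge
detection measures the blur, not the joint. **jsmap** measures JSW in 3D
at sub-voxel precision by fitting a physically motivated model of the
blurred joint to an interpolated density profile at every vertex of a
triangulated *joint space patch*, and deconvolving the blur under a fixed
peak-density constraint.

The package is aimed at quantitative musculoskeletal imaging researchers:
it takes a CT volume (NIfTI/MetaImage), a binary bone segmentation and a
joint-margin boundary polyline, and returns per-vertex JSW maps, femoral
and acetabular joint surface meshes, and agreement/reproducibility
statistics. A synthetic phantom generator with analytic ground truth makes
the whole chain testable end to end.

## The model

Density along a ray through the joint (HU, parameterised by `t` in mm along
the outward surface normal) is a piecewise-constant profile

```
y0 | y_peak | y_js | y_peak | y3        with edges x0 < x1 <= x2 < x3
```

(femoral interior, femoral cortex, joint tissue, acetabular cortex,
far side), convolved with a Gaussian PSF of standard deviation `sigma`:

```
f(t) = y0 + (y_peak - y0) Φ((t-x0)/σ) + (y_js - y_peak) Φ((t-x1)/σ)
          + (y_peak - y_js) Φ((t-x2)/σ) + (y3 - y_peak) Φ((t-x3)/σ)
```

with `Φ` the standard normal CDF. `y_js` is fixed at 35 HU (cartilage);
`y_peak` is fixed at a global peak cortical density estimated across the
whole bone surface; all other parameters are fitted per vertex by bounded
nonlinear least squares. The joint space width is `JSW = x2 − x1`, the
distance between the outer bone edges of the deconvolved (step) profile —
which is how widths below the PSF scale remain measurable. A companion
high-resolution method (`measure_half_max()`) implements the adaptive
half-maximum threshold used as reference on data with a much finer PSF.

## Worked example

Measure a clinical-regime synthetic hip (0.31 × 0.31 × 1.5 mm voxels,
clinical PSF, 20 HU noise) whose true gap rises smoothly from 1.5 mm at
the pole to 4.5 mm:

```r
library(jsmap)

gap_fun <- function(theta, phi)
  pmin(1.5 + 3.0 * (1 - cos(theta)) / (1 - cos(45 * pi / 180)), 4.5)
spec  <- phantom_spec("ball_socket", gap_function = gap_fun, seed = 7)
ph    <- generate_volume(spec)           # volume + femoral mask + boundary

mesh  <- mesh_from_mask(ph$mask)         # triangulated femoral surface
patch <- retriangulate(
  cut_patch(mesh, ph$boundary, seed = c(0, 0, 20)), 900)

map   <- measure_patch(patch, ph$volume, bone_mesh = mesh) |>
  remove_outliers() |>
  smooth_map()
map
#> jsw_map (jsm): 900 vertices, 900 ok
#>   JSW median 3.19 mm [1.42, 4.49]

glance(map)                             # one-row summary (tibble)
truth <- ground_truth_jsw(spec, patch)
agreement_report(map$jsw, truth)
#> agreement_report: n = 900, bias 0.013 mm, precision 0.135 mm,
#>   LoA +/- 0.264 mm, RMSCV 3.70%
```

The small residual bias, concentrated at the
narrowest gaps, is a documented property of the fixed-peak deconvolution at
slice-direction sampling; see the methods vignette
(`vignettes/joint-space-mapping.Rmd`) for the model assumptions, parameter
defaults and known limitations. `autoplot(map)` draws the JSW colour map;
`build_joint_surfaces(map)` exports the femoral/acetabular meshes that
bound the joint space volume.

A thin command-line wrapper is included at `inst/cli/jsmap.R`
(`phantom`, `measure`, `measure --hr`, `sample`, `agree` subcommands).

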