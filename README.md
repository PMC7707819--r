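# curvmap

Analysis of curvature-selective functional domains in intrinsic-signal
optical imaging of visual cortex.

Intrinsic-signal imaging measures stimulus-evoked reflectance changes of
cortex — fractional darkenings of 0.01–0.03 % peaking 2–3 s after stimulus
onset. Imaged with curved versus straight gratings, area V4 shows
sub-millimetre *curvature domains*: 200–500 µm patches that prefer curved
contours, sit inside the orientation bands, avoid pinwheel centres, and are
organised systematically by curvature degree and curve (apex) orientation.
curvmap implements the full analysis chain for such experiments, for
imaging labs and for anyone studying mesoscale cortical feature maps:

- **Stimuli** — ellipse-derived drifting curvature gratings (curvature
  index = axis ratio a/b), straight gratings as the exact a/b → 0 limit,
  flashed single lines, block-scrambled controls.
- **Synthetic cortex + imaging simulator** — planted orientation maps with
  pinwheels, colour/orientation bands, curvature domains, degree
  progressions; forward model `R = B(1+v)(1 − A·k(t) + drift + noise)` with
  a unit-peak gamma kernel (peak 2.5 s). Ground truth travels with every
  simulated session, so all downstream stages are tested by parameter
  recovery.
- **Maps** — per-pixel dR/R (`frame_drr`), per-trial responses (frames
  8–16 vs 1–3), paired t-maps `t = (mean_A − mean_B)·√N / S` with S the SD
  of per-trial differences (`difference_statistic_map`), and the field's
  two-scale spatial filtering (10 px FWHM Gaussian minus 120 px circular
  mean, `filter_map`).
- **Domains** — significance thresholding (two-tailed p < 0.01, activation
  sign, optional ANOVA + Tukey–Kramer gate), 8-connected labelling,
  morphometrics (size = πR², R = mean second-moment semi-axes, 0.2 mm
  minimum diameter), overlap percentages (IoU).
- **Feature maps** — orientation angle maps by vector averaging on the
  doubled angle; pinwheels by plaquette winding number.
- **Similarity / progression / timecourses** — ROI-restricted correlation
  matrices, correlation-vs-degree-difference regression, straight→curved
  nearest-domain progressions with centroid distances, domain-averaged
  timecourses with Wilcoxon rank-sum comparison on frames 9–18.

## Worked example

Simulate a session over a synthetic cortex with three planted curvature
domains, compute the curvature-vs-straight t-map, and recover the domains:

```r
library(curvmap)

model <- make_cortical_model(n_rows = 128, n_cols = 128, n_domains = 3,
                             amplitude_range = c(2e-4, 2e-4),
                             ratios = 5, curve_orientations = c("up", "down"),
                             seed = 42)
model
#> <cortical_model> 128 x 128 px at 0.01 mm/px ( 1.28 x 1.28 mm )
#>   curvature domains: 3  progressions: 0  pinwheels: 14
#>   orientation-band fraction: 0.6

battery <- list(
  curved_up   = stimulus_spec("curved_grating", curvature_ratio = 5,
                              curve_orientation = "up"),
  curved_down = stimulus_spec("curved_grating", curvature_ratio = 5,
                              curve_orientation = "down"),
  straight_0  = stimulus_spec("straight_grating", orientation_deg = 0),
  straight_90 = stimulus_spec("straight_grating", orientation_deg = 90))
session <- simulate_session(model, battery, n_trials = 30, seed = 43)

maps <- contrast_map(session, c("curved_up", "curved_down"),
                     c("straight_0", "straight_90"))
maps$t
#> <response_map> t_value 128x128 px  [ curved_up+curved_down vs straight_0+straight_90 ]
#>   range: -12.43 .. 4.047

domains <- filter_small_patches(
  detect_domains(maps$t, maps$p, sign = "negative", alpha = 0.01,
                 pixel_size_mm = model$pixel_size_mm),
  min_diameter_mm = 0.2)
domains$domains
#>   id area_mm2 eq_diam_mm centroid_row_mm centroid_col_mm n_pixels mean_t
#> 1  1   0.0709      0.300           0.869           0.270      656  -5.98
#> 2  2   0.0336      0.207           0.264           0.251      332  -5.44
#> 3  3   0.0706      0.300           0.357           0.562      698  -6.60

dice_coefficient(domains$label_image > 0, model$curvature_domain_mask)
#> [1] 0.8620366
```

The t-map is strongly negative (activation darkens the image) exactly at
the planted domains; all three are recovered with equivalent diameters in
the planted 0.2–0.3 mm range and a Dice agreement of 0.86 against the
planted masks. `plot(maps$t)`, `plot(domains)` and
`plot(orientation_angle_map(...))` display the maps;
`write_session()` / `read_session()` and `write_outputs()` handle the
on-disk TIFF + JSON format.

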