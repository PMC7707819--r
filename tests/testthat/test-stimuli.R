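# Stimulus synthesis: geometry of the ellipse-derived curvature gratings,
# straight-limit behaviour, flashed lines and block scrambling.

pp_odd <- 4 / 101 # odd grid => an exact central-axis (x = 0) column

test_that("curvature index is the axis ratio with validated inputs", {
  expect_equal(curvature_index(2, 1), 2)
  expect_equal(curvature_index(3, 3), 1)
  expect_equal(curvature_index(5, 1), 5)
  expect_error(curvature_index(0, 1), "positive")
  expect_error(curvature_index(2, -1), "positive")
})

test_that("central-axis profile is independent of curvature ratio", {
  f2 <- render_curved_grating(
    stimulus_spec("curved_grating", curvature_ratio = 2), 0, pp_odd)
  f5 <- render_curved_grating(
    stimulus_spec("curved_grating", curvature_ratio = 5), 0, pp_odd)
  cc <- (ncol(f2$luminance) + 1) / 2
  expect_lt(max(abs(f2$luminance[, cc] - f5$luminance[, cc])), 1e-12)
  # and the profile is the plain sinusoid of the nominal spatial frequency
  y <- (seq_len(nrow(f2$luminance)) - (nrow(f2$luminance) + 1) / 2) * pp_odd
  expect_equal(f2$luminance[, cc], 0.5 + 0.5 * sin(2 * pi * y),
               tolerance = 1e-12)
})

test_that("the straight grating is the zero-curvature limit", {
  sp <- stimulus_spec("curved_grating", curvature_ratio = 1e-12)
  st <- stimulus_spec("straight_grating", orientation_deg = 0)
  expect_equal(render_curved_grating(sp, 0.3, pp_odd)$luminance,
               render_straight_grating(st, 0.3, pp_odd)$luminance,
               tolerance = 1e-9)
})

test_that("apex orientations are exact reflections/rotations", {
  specs <- lapply(c("up", "down", "left", "right"), function(o)
    stimulus_spec("curved_grating", curvature_ratio = 2,
                  curve_orientation = o))
  fr <- lapply(specs, render_curved_grating, t = 0.1,
               pixel_pitch_deg = pp_odd)
  up <- fr[[1]]$luminance
  expect_identical(fr[[2]]$luminance, up[nrow(up):1, ])    # mirror
  expect_identical(fr[[3]]$luminance, t(up)[ncol(up):1, ]) # 90 deg ccw
  expect_identical(fr[[4]]$luminance, t(up[nrow(up):1, ])) # 90 deg cw
})

test_that("straight gratings are 180-periodic in orientation with mean 0.5", {
  a <- render_straight_grating(
    stimulus_spec("straight_grating", orientation_deg = 30), 0, 0.01)
  b <- render_straight_grating(
    stimulus_spec("straight_grating", orientation_deg = 210), 0, 0.01)
  expect_identical(a$luminance, b$luminance)
  # whole number of periods across the 4 deg field at 1 c/deg
  expect_equal(mean(render_straight_grating(
    stimulus_spec("straight_grating"), 0, 0.01)$luminance), 0.5,
    tolerance = 1e-3)
})

test_that("frames drift periodically and stay within [0, 1]", {
  sp <- stimulus_spec("curved_grating", curvature_ratio = 5, sf_cpd = 1,
                      drift_speed_deg_s = 2)
  period <- 1 / (sp$sf_cpd * sp$drift_speed_deg_s)
  f0 <- render_curved_grating(sp, 0.2, 0.02)$luminance
  f1 <- render_curved_grating(sp, 0.2 + period, 0.02)$luminance
  expect_equal(f0, f1, tolerance = 1e-9)
  for (kind in c("curved_grating", "straight_grating", "scrambled_grating")) {
    sp <- stimulus_spec(kind, curvature_ratio =
                          if (kind == "straight_grating") 0 else 3)
    lum <- render_stimulus(sp, 0.37, 0.02)$luminance
    expect_true(all(lum >= 0 & lum <= 1))
  }
})

test_that("local flank frequency rises towards the edge, faster for sharper curvature", {
  # mean |d phase/dx| along a horizontal cut is sf * |Delta'(x)|
  flank_freq <- function(ratio, xfrac) {
    b <- 2
    a <- ratio * b
    x <- xfrac * b
    1 * a * x / (b^2 * sqrt(1 - (x / b)^2))
  }
  for (r in c(2, 5)) {
    expect_lt(flank_freq(r, 0.5), flank_freq(r, 0.9))
  }
  expect_lt(flank_freq(2, 0.9), flank_freq(5, 0.9))
  # and empirically on rendered frames: luminance changes along a row are
  # faster near the edge for the sharper grating
  grad_near_edge <- function(ratio) {
    f <- render_curved_grating(
      stimulus_spec("curved_grating", curvature_ratio = ratio), 0,
      pp_odd)$luminance
    rowcut <- f[(nrow(f) + 1) / 2, ]
    mean(abs(diff(rowcut[1:15])))
  }
  expect_gt(grad_near_edge(5), grad_near_edge(2))
})

test_that("flashed lines render a single contour with curvature-dependent arc length", {
  sp <- stimulus_spec("straight_line", orientation_deg = 0,
                      line_width_deg = 0.05)
  off <- render_flashed_line(sp, on = FALSE, pixel_pitch_deg = pp_odd)
  expect_true(all(off$luminance == 0))
  on <- render_flashed_line(sp, on = TRUE, pixel_pitch_deg = pp_odd)
  rows_lit <- which(apply(on$luminance > 0, 1, any))
  expect_true(all(diff(rows_lit) == 1)) # one contiguous horizontal band
  expect_lt(length(rows_lit), 5)
  # arc length of the rendered curve grows with the curvature ratio
  arc <- function(ratio) {
    b <- 2
    a <- ratio * b
    f <- function(x) sqrt(1 + (a * x / (b^2 * sqrt(1 - (x / b)^2)))^2)
    stats::integrate(f, -0.99 * b, 0.99 * b)$value
  }
  expect_gt(arc(5), arc(2))
  # curved-line frames are binary with the vertex at the stimulus centre
  cl <- render_flashed_line(stimulus_spec("curved_line",
                                          curvature_ratio = 2,
                                          line_width_deg = 0.1),
                            pixel_pitch_deg = pp_odd)
  expect_true(all(cl$luminance %in% c(0, 1)))
  mid <- (nrow(cl$luminance) + 1) / 2
  expect_equal(cl$luminance[mid, mid], 1)
})

test_that("scrambling is an exact block permutation", {
  f <- render_curved_grating(
    stimulus_spec("curved_grating", curvature_ratio = 2), 0, 0.01)
  # identity permutation reproduces the (crop-free) input
  id <- scramble_stimulus(f, 64, permutation = 1:64)
  expect_identical(id$luminance, f$luminance)
  # any seed preserves the pixel-value multiset exactly
  s <- scramble_stimulus(f, 64, seed = 9)
  expect_identical(sort(as.vector(s$luminance)),
                   sort(as.vector(f$luminance)))
  expect_false(identical(s$luminance, f$luminance))
  # the stored permutation inverts bit-exactly
  p <- attr(s, "scramble_permutation")
  expect_length(p, 64)
  back <- scramble_stimulus(s, 64, permutation = order(p))
  expect_identical(back$luminance, f$luminance)
  expect_error(scramble_stimulus(f, 60), "perfect square")
  # non-divisible dimensions centre-crop to the largest divisible size
  g <- render_curved_grating(
    stimulus_spec("curved_grating", curvature_ratio = 2), 0, pp_odd)
  sg <- scramble_stimulus(g, 64, seed = 1)
  expect_equal(dim(sg$luminance), c(96, 96))
  expect_identical(sort(as.vector(sg$luminance)),
                   sort(as.vector(g$luminance[3:98, 3:98])))
})

test_that("stimulus specs validate their invariants", {
  expect_error(stimulus_spec("curved_grating", curvature_ratio = 0),
               "curvature_ratio > 0")
  expect_error(stimulus_spec("straight_grating", curvature_ratio = 2),
               "curvature_ratio = 0")
  expect_error(stimulus_spec("curved_grating", n_scramble_subunits = 50),
               "perfect square")
  expect_error(stimulus_spec("curved_grating", curve_orientation = "diag"),
               "up/down/left/right")
  cyc <- render_drift_cycle(stimulus_spec("curved_grating",
                                          curvature_ratio = 2),
                            n_frames = 4, pixel_pitch_deg = 0.04)
  expect_length(cyc, 4)
})
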