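# Stimulus synthesis: ellipse-derived curvature gratings, straight gratings,
# flashed single lines, and block-scrambled controls.
#
# Curved contours derive from the ellipse X^2/a^2 + Y^2/b^2 = 1 with long
# axis a and short axis b; the curvature index is the axis ratio a/b (0 is
# the straight limit).  A grating is built from the vertical displacement
# field of the half-ellipse, Delta(x) = a*(1 - sqrt(1 - x^2/b^2)) with
# b = half the stimulus width and a = ratio*b, so the central-axis (x = 0)
# profile is a plain sinusoid whose spatial frequency does not depend on the
# curvature ratio, while the local frequency on the flanks grows with the
# ratio.  Apex curvature is a/b^2, monotone in the ratio.

#' Curvature index of an ellipse
#'
#' The curvature index (curvature degree) of a curved contour generated from
#' an ellipse is the ratio of the long axis to the short axis, `a/b`.  A
#' circle has index 1; larger values give sharper apices; the straight-line
#' limit is index 0.
#'
#' @param a Long-axis length (same units as `b`), positive.
#' @param b Short-axis length (half the contour width), positive.
#' @return The dimensionless ratio `a/b`.
#' @examples
#' curvature_index(2, 1) # 2
#' curvature_index(5, 1) # 5
#' @export
curvature_index <- function(a, b) {
  if (!is.numeric(a) || !is.numeric(b) || any(!is.finite(a)) ||
      any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop("ellipse axes `a` and `b` must be positive", call. = FALSE)
  a / b
}

#' Parametric stimulus description
#'
#' Construct the parameter record for one stimulus condition.  The record is
#' consumed by [render_stimulus()] and by the synthetic-cortex tuning model
#' ([tuning_response()]).
#'
#' @param kind One of `"curved_grating"`, `"straight_grating"`,
#'   `"curved_line"`, `"straight_line"`, `"scrambled_grating"`, `"blank"`.
#' @param curvature_ratio Curvature index a/b (>= 0); must be 0 for straight
#'   kinds and positive for curved/scrambled kinds.
#' @param curve_orientation Direction the curve apex points:
#'   `"up"`, `"down"`, `"left"` or `"right"` (curved kinds only).
#' @param orientation_deg Contour orientation in degrees for straight kinds,
#'   180-periodic (0 = horizontal contours).
#' @param sf_cpd Spatial frequency along the central axis, cycles/degree.
#' @param size_deg Stimulus extent in degrees (square field).
#' @param drift_speed_deg_s Drift speed, degrees/second.
#' @param phase Spatial phase, radians.
#' @param line_width_deg Line thickness for flashed-line kinds, degrees.
#' @param chromatic Logical tag marking an isoluminant colour stimulus
#'   (rendering is always achromatic; the tag drives the colour-band gate of
#'   the tuning model).
#' @param n_scramble_subunits Number of scramble blocks (perfect square).
#' @param seed Integer seed for the scramble permutation.
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec("curved_grating", curvature_ratio = 5, curve_orientation = "up")
#' @export
stimulus_spec <- function(kind = c("curved_grating", "straight_grating",
                                   "curved_line", "straight_line",
                                   "scrambled_grating", "blank"),
                          curvature_ratio = NULL,
                          curve_orientation = "up",
                          orientation_deg = 0,
                          sf_cpd = 1,
                          size_deg = 4,
                          drift_speed_deg_s = 2,
                          phase = 0,
                          line_width_deg = 0.05,
                          chromatic = FALSE,
                          n_scramble_subunits = 64L,
                          seed = 1L) {
  kind <- match.arg(kind)
  curved <- kind %in% c("curved_grating", "curved_line", "scrambled_grating")
  if (is.null(curvature_ratio)) curvature_ratio <- if (curved) 2 else 0
  if (kind != "blank") {
    stopifnot_scalar_pos(sf_cpd, "sf_cpd")
    stopifnot_scalar_pos(size_deg, "size_deg")
  }
  if (curved && curvature_ratio <= 0)
    stop("curved stimuli require curvature_ratio > 0", call. = FALSE)
  if (!curved && curvature_ratio != 0)
    stop("straight/blank stimuli require curvature_ratio = 0", call. = FALSE)
  if (!curve_orientation %in% c("up", "down", "left", "right"))
    stop("curve_orientation must be up/down/left/right", call. = FALSE)
  rt <- sqrt(n_scramble_subunits)
  if (rt != as.integer(rt))
    stop("n_scramble_subunits must be a perfect square", call. = FALSE)
  structure(list(kind = kind,
                 curvature_ratio = curvature_ratio,
                 curve_orientation = curve_orientation,
                 orientation_deg = orientation_deg %% 180,
                 sf_cpd = sf_cpd,
                 size_deg = size_deg,
                 drift_speed_deg_s = drift_speed_deg_s,
                 phase = phase,
                 line_width_deg = line_width_deg,
                 chromatic = isTRUE(chromatic),
                 n_scramble_subunits = as.integer(n_scramble_subunits),
                 seed = as.integer(seed)),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec>", x$kind, "\n")
  if (x$kind %in% c("curved_grating", "curved_line", "scrambled_grating"))
    cat("  curvature ratio a/b:", x$curvature_ratio,
        " apex:", x$curve_orientation, "\n")
  if (x$kind %in% c("straight_grating", "straight_line"))
    cat("  orientation:", x$orientation_deg, "deg\n")
  cat("  sf:", x$sf_cpd, "c/deg  size:", x$size_deg, "deg  drift:",
      x$drift_speed_deg_s, "deg/s", if (x$chromatic) " chromatic" else "", "\n")
  invisible(x)
}

# Half-ellipse displacement field Delta(x), the vertical offset of the
# curved contour at horizontal position x (|x| <= b by construction).
ellipse_displacement <- function(x, ratio, half_width) {
  a <- ratio * half_width
  arg <- pmax(0, 1 - (x / half_width)^2)
  a * (1 - sqrt(arg))
}

new_stimulus_frame <- function(luminance, pixel_pitch_deg, spec, t = 0) {
  structure(list(luminance = luminance,
                 pixel_pitch_deg = pixel_pitch_deg,
                 spec = spec, t = t),
            class = "stimulus_frame")
}

#' @export
print.stimulus_frame <- function(x, ...) {
  cat("<stimulus_frame>", x$spec$kind, paste(dim(x$luminance), collapse = "x"),
      "px,", x$pixel_pitch_deg, "deg/px, t =", x$t, "s\n")
  invisible(x)
}

#' @export
plot.stimulus_frame <- function(x, ...) {
  graphics::image(t(flip_ud(x$luminance)), col = grDevices::gray(0:255 / 255),
                  zlim = c(0, 1), asp = 1, axes = FALSE, ...)
  invisible(x)
}

# Canonical apex-up curved grating; other apex directions are exact
# flips/rotations of this frame (rotational closure on square grids).
render_curved_up <- function(spec, t, pixel_pitch_deg) {
  n <- round(spec$size_deg / pixel_pitch_deg)
  ax <- centered_axis(n, pixel_pitch_deg)
  b <- spec$size_deg / 2
  delta <- ellipse_displacement(ax, spec$curvature_ratio, b)
  u <- outer(ax, delta, "+") # u[i, j] = y_i + Delta(x_j)
  0.5 + 0.5 * sin(2 * pi * spec$sf_cpd * (u - spec$drift_speed_deg_s * t) +
                    spec$phase)
}

orient_frame <- function(m, curve_orientation) {
  switch(curve_orientation,
         up = m,
         down = flip_ud(m),
         left = rot90_ccw(m),
         right = rot90_cw(m))
}

#' Render a drifting curvature grating
#'
#' Luminance is `0.5 + 0.5*sin(2*pi*sf*(u - v*t) + phase)` with phase
#' coordinate `u(x, y) = y + Delta(x)`, where `Delta` is the half-ellipse
#' displacement field (apex-up canonical frame; other apex directions are
#' exact reflections/rotations).  The central-axis profile is a sinusoid of
#' frequency `sf_cpd` independent of the curvature ratio.
#'
#' @param spec A [stimulus_spec()] with kind `"curved_grating"`.
#' @param t Time in seconds (drift phase).
#' @param pixel_pitch_deg Rendering resolution, degrees/pixel.
#' @return A `stimulus_frame` with luminance values in `[0, 1]`.
#' @export
render_curved_grating <- function(spec, t = 0, pixel_pitch_deg = 0.01) {
  if (spec$kind != "curved_grating")
    stop("spec kind must be curved_grating", call. = FALSE)
  m <- orient_frame(render_curved_up(spec, t, pixel_pitch_deg),
                    spec$curve_orientation)
  new_stimulus_frame(m, pixel_pitch_deg, spec, t)
}

#' Render a drifting straight grating
#'
#' The straight grating shares luminance, drift speed and central-axis
#' spatial frequency with the curvature gratings; it equals the curvature
#' grating in the limit `curvature_ratio -> 0`.
#'
#' @inheritParams render_curved_grating
#' @param spec A [stimulus_spec()] with kind `"straight_grating"`.
#' @return A `stimulus_frame`.
#' @export
render_straight_grating <- function(spec, t = 0, pixel_pitch_deg = 0.01) {
  if (spec$kind != "straight_grating")
    stop("spec kind must be straight_grating", call. = FALSE)
  n <- round(spec$size_deg / pixel_pitch_deg)
  ax <- centered_axis(n, pixel_pitch_deg)
  th <- spec$orientation_deg * pi / 180
  u <- outer(ax * cos(th), ax * sin(th), "+")
  m <- 0.5 + 0.5 * sin(2 * pi * spec$sf_cpd *
                         (u - spec$drift_speed_deg_s * t) + spec$phase)
  new_stimulus_frame(m, pixel_pitch_deg, spec, t)
}

#' Render a flashed single line (curved or straight)
#'
#' A single bright contour on a dark background (the vertex of curved lines
#' is fixed at the stimulus centre), or an all-dark frame in the off phase of
#' the flash cycle.
#'
#' @inheritParams render_curved_grating
#' @param spec A [stimulus_spec()] with kind `"curved_line"` or
#'   `"straight_line"`.
#' @param on Logical; `FALSE` renders the interleaved blank (all zeros).
#' @return A `stimulus_frame`.
#' @export
render_flashed_line <- function(spec, on = TRUE, pixel_pitch_deg = 0.01) {
  if (!spec$kind %in% c("curved_line", "straight_line"))
    stop("spec kind must be curved_line or straight_line", call. = FALSE)
  n <- round(spec$size_deg / pixel_pitch_deg)
  if (!on)
    return(new_stimulus_frame(matrix(0, n, n), pixel_pitch_deg, spec, 0))
  ax <- centered_axis(n, pixel_pitch_deg)
  hw <- spec$line_width_deg / 2
  if (spec$kind == "curved_line") {
    b <- spec$size_deg / 2
    delta <- ellipse_displacement(ax, spec$curvature_ratio, b)
    dist <- abs(outer(ax, delta, "-")) # |y_i - Delta(x_j)|
    m <- orient_frame((dist <= hw) * 1, spec$curve_orientation)
  } else {
    th <- spec$orientation_deg * pi / 180
    u <- outer(ax * cos(th), ax * sin(th), "+")
    m <- (abs(u) <= hw) * 1
  }
  new_stimulus_frame(m, pixel_pitch_deg, spec, 0)
}

#' Block-scramble a stimulus frame
#'
#' Divides the frame into `n_subunits` square blocks (an sqrt(n) x sqrt(n)
#' grid) and randomly rearranges the block locations.  The pixel-value
#' multiset is preserved exactly.  Frames whose dimensions are not divisible
#' by the block grid are centre-cropped to the largest divisible size so the
#' permutation is exact.
#'
#' @param frame A `stimulus_frame` (or plain matrix).
#' @param n_subunits Number of blocks; must be a perfect square.
#' @param seed Integer seed for the permutation (default: the spec's seed).
#' @param permutation Optional explicit permutation of `seq_len(n_subunits)`
#'   (block destination order); overrides `seed`.
#' @return A `stimulus_frame` whose luminance is the block-permuted input;
#'   the permutation used is stored in attribute `"scramble_permutation"`.
#' @export
scramble_stimulus <- function(frame, n_subunits = 64L, seed = NULL,
                              permutation = NULL) {
  rt <- sqrt(n_subunits)
  if (rt != as.integer(rt))
    stop("n_subunits must be a perfect square", call. = FALSE)
  rt <- as.integer(rt)
  m <- if (inherits(frame, "stimulus_frame")) frame$luminance else frame
  nr <- (nrow(m) %/% rt) * rt
  nc <- (ncol(m) %/% rt) * rt
  r0 <- (nrow(m) - nr) %/% 2
  c0 <- (ncol(m) - nc) %/% 2
  m <- m[r0 + seq_len(nr), c0 + seq_len(nc), drop = FALSE]
  br <- nr %/% rt
  bc <- nc %/% rt
  if (is.null(permutation)) {
    if (is.null(seed) && inherits(frame, "stimulus_frame"))
      seed <- frame$spec$seed
    permutation <- with_seed(seed, sample.int(rt * rt))
  }
  if (length(permutation) != rt * rt || !setequal(permutation, seq_len(rt * rt)))
    stop("permutation must be a permutation of seq_len(n_subunits)",
         call. = FALSE)
  out <- matrix(0, nr, nc)
  for (k in seq_len(rt * rt)) {
    src <- permutation[k]
    si <- (src - 1L) %/% rt
    sj <- (src - 1L) %% rt
    di <- (k - 1L) %/% rt
    dj <- (k - 1L) %% rt
    out[di * br + seq_len(br), dj * bc + seq_len(bc)] <-
      m[si * br + seq_len(br), sj * bc + seq_len(bc)]
  }
  res <- if (inherits(frame, "stimulus_frame")) {
    new_stimulus_frame(out, frame$pixel_pitch_deg, frame$spec, frame$t)
  } else new_stimulus_frame(out, NA_real_, NULL, 0)
  attr(res, "scramble_permutation") <- permutation
  res
}

#' Render any stimulus condition
#'
#' Dispatcher over the stimulus kinds: drifting curved/straight gratings,
#' flashed lines (rendered in their on phase), scrambled curvature gratings
#' (rendered, then block-permuted under the spec's seed) and the blank screen
#' (uniform mid-gray).
#'
#' @inheritParams render_curved_grating
#' @param spec A [stimulus_spec()].
#' @return A `stimulus_frame`.
#' @export
render_stimulus <- function(spec, t = 0, pixel_pitch_deg = 0.01) {
  switch(spec$kind,
         curved_grating = render_curved_grating(spec, t, pixel_pitch_deg),
         straight_grating = render_straight_grating(spec, t, pixel_pitch_deg),
         curved_line = ,
         straight_line = render_flashed_line(spec, TRUE, pixel_pitch_deg),
         scrambled_grating = {
           base <- spec
           base$kind <- "curved_grating"
           scramble_stimulus(render_curved_grating(base, t, pixel_pitch_deg),
                             spec$n_scramble_subunits, seed = spec$seed)
         },
         blank = {
           n <- round(spec$size_deg / pixel_pitch_deg)
           new_stimulus_frame(matrix(0.5, n, n), pixel_pitch_deg, spec, t)
         })
}

#' Render one full drift cycle
#'
#' Frames sampled over one temporal period `1/(sf_cpd * drift_speed_deg_s)`;
#' the frame after the last returns to the first (drift periodicity).
#'
#' @inheritParams render_stimulus
#' @param n_frames Number of frames over the cycle.
#' @return A list of `stimulus_frame` objects.
#' @export
render_drift_cycle <- function(spec, n_frames = 16, pixel_pitch_deg = 0.01) {
  period <- 1 / (spec$sf_cpd * spec$drift_speed_deg_s)
  lapply(seq_len(n_frames) - 1L,
         function(k) render_stimulus(spec, t = k * period / n_frames,
                                     pixel_pitch_deg = pixel_pitch_deg))
}
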