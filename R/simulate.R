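# Forward model of intrinsic-signal image acquisition over a synthetic
# cortex.  Activation *darkens* the image (reflectance decrease), following
# the intrinsic-signal sign convention; the temporal profile is a
# gamma-shaped hemodynamic kernel peaking 2-3 s after stimulus onset.

#' Noise specification for the imaging simulator
#'
#' @param pixel_noise_sd Per-frame, per-pixel white-noise SD in reflectance
#'   fraction units.  The default, 1e-3, is five times the default 2e-4 peak
#'   signal amplitude, so that ~30 trials of averaging yield clear maps.
#' @param drift_amplitude Amplitude of a slow global (spatially uniform)
#'   reflectance drift, fraction units.
#' @param drift_timescale_s Drift period, seconds; the minutes-scale
#'   default mimics slow illumination/physiological drift, which largely
#'   cancels within a trial under the pre-stimulus dR/R normalisation.
#' @param vascular_contrast Amplitude of a static smooth spatial pattern
#'   multiplying the baseline (a stand-in for vascular/illumination
#'   structure; constant over frames, so it cancels in dR/R).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(pixel_noise_sd = 1e-3,
                       drift_amplitude = 2e-4,
                       drift_timescale_s = 60,
                       vascular_contrast = 0.05) {
  stopifnot(pixel_noise_sd >= 0, drift_amplitude >= 0,
            vascular_contrast >= 0, drift_timescale_s > 0)
  structure(list(pixel_noise_sd = pixel_noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_timescale_s = drift_timescale_s,
                 vascular_contrast = vascular_contrast),
            class = "noise_spec")
}

#' Gamma-shaped hemodynamic response kernel
#'
#' Gamma-density time profile normalised to unit peak, with the mode
#' (peak time) at `peak_s` after stimulus onset; zero before onset.
#'
#' @param t_s Times since stimulus onset, seconds.
#' @param peak_s Peak time, seconds (default 2.5, within the 2-3 s range
#'   typical of intrinsic signals).
#' @param shape Gamma shape parameter (larger = narrower kernel).
#' @return Kernel values in `[0, 1]`.
#' @export
hemodynamic_kernel <- function(t_s, peak_s = 2.5, shape = 5) {
  scale <- peak_s / (shape - 1)
  peak <- stats::dgamma(peak_s, shape = shape, scale = scale)
  ifelse(t_s > 0, stats::dgamma(t_s, shape = shape, scale = scale) / peak, 0)
}

# Frame mid-times relative to stimulus onset.  Imaging starts 0.5 s before
# onset (n_prestim frames at the acquisition rate); frame f (1-based)
# spans [(f-1)/rate, f/rate] of imaging time.
frame_times_s <- function(n_frames, frame_rate_hz, n_prestim_frames) {
  (seq_len(n_frames) - 0.5) / frame_rate_hz - n_prestim_frames / frame_rate_hz
}

#' Simulate an intrinsic-signal imaging session
#'
#' For each condition and trial, reflectance is
#' `baseline * vascular * (1 - A*k(t) + drift(t) + noise)`, where `A` is the
#' per-pixel peak tuning response ([tuning_response()]) and `k` the unit-peak
#' hemodynamic kernel -- activation darkens the image.  Trials are
#' independent given the seed stream; the session is bit-identical for a
#' given seed.
#'
#' @param model A [make_cortical_model()] object.
#' @param condition_table Named list of [stimulus_spec()] objects, one per
#'   condition.
#' @param n_trials Trials per condition (the field standard is >= 30).
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @param frame_rate_hz Acquisition rate, Hz.
#' @param n_prestim_frames Frames acquired before stimulus onset.
#' @param stim_duration_s Stimulus duration, seconds (4.5 for curvature
#'   batteries, 3.5 for colour/high-SF batteries).
#' @param baseline Mean raw reflectance level (arbitrary units, > 0).
#' @param keep_truth Store the generating model in the session
#'   (`$ground_truth`) for parameter-recovery analyses.
#' @return An [imaging_session()] object.  Data are stored per condition as
#'   arrays indexed `[row, col, frame, trial]`.
#' @export
simulate_session <- function(model, condition_table, n_trials = 30,
                             noise = noise_spec(), seed = 1L,
                             frame_rate_hz = 4, n_prestim_frames = 2,
                             stim_duration_s = 4.5, baseline = 1,
                             keep_truth = TRUE) {
  stopifnot(inherits(model, "cortical_model"), n_trials >= 1,
            length(condition_table) >= 1)
  if (is.null(names(condition_table)) || anyDuplicated(names(condition_table)))
    stop("condition_table must be a uniquely named list", call. = FALSE)
  n_frames <- n_prestim_frames + round(stim_duration_s * frame_rate_hz)
  tt <- frame_times_s(n_frames, frame_rate_hz, n_prestim_frames)
  k <- hemodynamic_kernel(tt)
  nr <- model$n_rows; nc <- model$n_cols; npx <- nr * nc
  data <- with_seed(seed, {
    vasc <- 1 + noise$vascular_contrast *
      smooth_noise_field(nr, nc, 6)
    lapply(condition_table, function(spec) {
      A <- tuning_response(model, spec)
      core <- outer(as.vector(-A), k) # npx x n_frames signal term
      arr <- array(0, dim = c(nr, nc, n_frames, n_trials))
      for (tr in seq_len(n_trials)) {
        phi <- stats::runif(1, 0, 2 * pi)
        drift <- noise$drift_amplitude *
          sin(2 * pi * (tt + n_prestim_frames / frame_rate_hz) /
                noise$drift_timescale_s + phi)
        eps <- matrix(stats::rnorm(npx * n_frames, sd = noise$pixel_noise_sd),
                      npx, n_frames)
        fr <- 1 + core + rep(drift, each = npx) + eps
        arr[, , , tr] <- baseline * as.vector(vasc) * fr
      }
      arr
    })
  })
  imaging_session(data = data, condition_table = condition_table,
                  frame_rate_hz = frame_rate_hz,
                  n_prestim_frames = n_prestim_frames,
                  stim_duration_s = stim_duration_s,
                  pixel_size_mm = model$pixel_size_mm,
                  seed = as.integer(seed),
                  ground_truth = if (keep_truth) model else NULL)
}

#' Imaging session container
#'
#' The central container consumed by every analysis stage: reflectance data
#' per condition (arrays indexed `[row, col, frame, trial]`) plus
#' acquisition metadata.
#'
#' @param data Named list of 4-D reflectance arrays, one per condition.
#' @param condition_table Named list of [stimulus_spec()] objects matching
#'   `names(data)`.
#' @param frame_rate_hz,n_prestim_frames,stim_duration_s,pixel_size_mm
#'   Acquisition metadata.
#' @param seed Generator seed (provenance; `NA` for acquired data).
#' @param ground_truth Optional [make_cortical_model()] ground truth.
#' @return An object of class `imaging_session`.
#' @export
imaging_session <- function(data, condition_table, frame_rate_hz = 4,
                            n_prestim_frames = 2, stim_duration_s = 4.5,
                            pixel_size_mm, seed = NA_integer_,
                            ground_truth = NULL) {
  stopifnot(is.list(data), length(data) >= 1,
            !is.null(names(data)),
            setequal(names(data), names(condition_table)))
  n_frames_expected <- n_prestim_frames + round(stim_duration_s * frame_rate_hz)
  for (nm in names(data)) {
    d <- dim(data[[nm]])
    if (length(d) != 4)
      stop("condition ", nm, ": data must be [row, col, frame, trial]",
           call. = FALSE)
    if (d[3] != n_frames_expected)
      stop(sprintf(
        "condition %s: %d frames found, %d expected from metadata",
        nm, d[3], n_frames_expected), call. = FALSE)
    if (any(data[[nm]] <= 0))
      stop("condition ", nm, ": reflectance values must be positive",
           call. = FALSE)
  }
  structure(list(data = data, condition_table = condition_table,
                 frame_rate_hz = frame_rate_hz,
                 n_prestim_frames = n_prestim_frames,
                 stim_duration_s = stim_duration_s,
                 n_frames = n_frames_expected,
                 pixel_size_mm = pixel_size_mm,
                 n_trials = dim(data[[1]])[4],
                 seed = seed,
                 ground_truth = ground_truth),
            class = "imaging_session")
}

#' @export
print.imaging_session <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat("<imaging_session>", length(x$data), "conditions,",
      d[4], "trials,", d[3], "frames of", d[1], "x", d[2], "px\n")
  cat("  ", x$frame_rate_hz, "Hz,", x$n_prestim_frames, "pre-stimulus frames,",
      x$stim_duration_s, "s stimulus,", x$pixel_size_mm, "mm/px\n")
  cat("  conditions:", paste(names(x$data), collapse = ", "), "\n")
  if (!is.null(x$ground_truth)) cat("  ground truth attached\n")
  invisible(x)
}

#' Conditions of a session
#' @param session An [imaging_session()].
#' @return Character vector of condition ids.
#' @export
conditions <- function(session) names(session$data)
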