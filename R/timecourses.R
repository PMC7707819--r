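# Domain-averaged response timecourses and their statistical comparison.

#' Extract a domain-averaged timecourse
#'
#' Per trial, the per-frame dR/R ([frame_drr()], baseline = mean of the
#' first two, pre-stimulus, frames) is averaged over the mask pixels; the
#' timecourse is the mean over trials with its SEM.  Optionally the mask is
#' first gated to pixels significantly activated versus blank (`p < alpha`,
#' negative paired t on trial responses) -- the conventional
#' significant-pixel gate for domain timecourses.
#'
#' @param session An [imaging_session()].
#' @param condition Condition id whose timecourse is extracted.
#' @param mask Logical matrix of domain pixels.
#' @param blank_condition Optional blank condition id enabling the
#'   significance gate.
#' @param alpha Gate significance level.
#' @param n_baseline_frames Baseline frames for dR/R.
#' @return Object of class `timecourse`: data.frame `frames` (frame, mean,
#'   sem) plus `n_pixels`, `n_trials`, `condition`, and the per-trial frame
#'   matrix `trial_frames` (trials x frames) for downstream statistics.
#' @export
extract_domain_timecourse <- function(session, condition, mask,
                                      blank_condition = NULL, alpha = 0.01,
                                      n_baseline_frames = 2) {
  stopifnot(inherits(session, "imaging_session"))
  if (!condition %in% conditions(session))
    stop("unknown condition: ", condition, call. = FALSE)
  if (!is.null(blank_condition)) {
    a <- trial_response_maps(session, condition)
    b <- trial_response_maps(session, blank_condition)
    st <- difference_statistic_map(a, b, paired = TRUE)
    mask <- mask & st$p$values < alpha & st$t$values < 0
    if (!any(mask))
      stop("no mask pixels survive the significant-vs-blank gate (p < ",
           alpha, ")", call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  stack <- session$data[[condition]]
  d <- dim(stack)
  drr <- frame_drr(stack, n_baseline_frames)
  dim(drr) <- c(d[1] * d[2], d[3], d[4])
  sel <- drr[as.vector(mask), , , drop = FALSE]
  per_trial <- apply(sel, c(2, 3), mean) # frames x trials
  m <- rowMeans(per_trial)
  sem <- apply(per_trial, 1, stats::sd) / sqrt(d[4])
  structure(list(frames = data.frame(frame = seq_len(d[3]), mean = m,
                                     sem = sem),
                 trial_frames = t(per_trial),
                 n_pixels = sum(mask), n_trials = d[4],
                 condition = condition,
                 frame_rate_hz = session$frame_rate_hz),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat("<timecourse>", x$condition, ":", nrow(x$frames), "frames,",
      x$n_pixels, "pixels,", x$n_trials, "trials\n")
  cat("  peak |dR/R|:", signif(max(abs(x$frames$mean)), 3), "at frame",
      which.max(abs(x$frames$mean)), "\n")
  invisible(x)
}

#' @export
plot.timecourse <- function(x, col = "black", add = FALSE, ylim = NULL, ...) {
  f <- x$frames
  if (is.null(ylim))
    ylim <- range(c(f$mean - f$sem, f$mean + f$sem))
  if (!add)
    plot(f$frame, f$mean, type = "n", xlab = "frame", ylab = "dR/R",
         ylim = ylim, ...)
  graphics::polygon(c(f$frame, rev(f$frame)),
                    c(f$mean - f$sem, rev(f$mean + f$sem)),
                    border = NA,
                    col = grDevices::adjustcolor(col, alpha.f = 0.2))
  graphics::lines(f$frame, f$mean, col = col)
  invisible(x)
}

#' Window amplitude of a timecourse
#'
#' Response amplitude over a frame window, reported activation-positive
#' (the negative of the mean dR/R over the window).
#'
#' @param tc A `timecourse`.
#' @param frame_window `c(first, last)`, 1-based inclusive.
#' @return Scalar amplitude.
#' @export
timecourse_amplitude <- function(tc, frame_window = c(9, 18)) {
  fw <- clip_window(frame_window, nrow(tc$frames))
  -mean(tc$frames$mean[fw[1]:fw[2]])
}

clip_window <- function(frame_window, n_frames) {
  if (frame_window[1] > n_frames)
    stop("frame window starts beyond the stack", call. = FALSE)
  if (frame_window[2] > n_frames) {
    warning(sprintf("frame window clipped to (%d, %d)",
                    frame_window[1], n_frames))
    frame_window[2] <- n_frames
  }
  frame_window
}

#' Compare two timecourses over a frame window
#'
#' Wilcoxon rank-sum test on the per-frame mean values within the window
#' (1-based frames 9-18 by convention for 4.5 s stimuli; clipped with a
#' warning for shorter sessions).  This is the field's procedure; note the
#' frames within a window are autocorrelated, so the p-value is
#' descriptive rather than strictly calibrated.
#'
#' @param tc_a,tc_b `timecourse` objects (or plain numeric per-frame
#'   vectors).
#' @param frame_window `c(first, last)`, 1-based inclusive.
#' @param exact Use the exact rank-sum distribution (default for n <= 10
#'   per group, following `wilcox.test`).
#' @return List with `p_value`, `median_difference` (A - B over the
#'   window), `statistic` (rank-sum W) and the window used.
#' @export
compare_timecourses <- function(tc_a, tc_b, frame_window = c(9, 18),
                                exact = NULL) {
  va <- if (inherits(tc_a, "timecourse")) tc_a$frames$mean else tc_a
  vb <- if (inherits(tc_b, "timecourse")) tc_b$frames$mean else tc_b
  fw <- clip_window(frame_window, min(length(va), length(vb)))
  a <- va[fw[1]:fw[2]]; b <- vb[fw[1]:fw[2]]
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact))
  list(p_value = wt$p.value,
       median_difference = stats::median(a) - stats::median(b),
       statistic = unname(wt$statistic),
       frame_window = fw)
}

#' Response-amplitude summary across domain and stimulus classes
#'
#' For every (domain class, stimulus class) cell: the mean window amplitude
#' (activation-positive) of the domain-averaged timecourse, its dispersion
#' over trials, and -- against the domain class's preferred stimulus class
#' -- the rank-sum comparison of [compare_timecourses()].
#'
#' @param session An [imaging_session()].
#' @param domain_masks Named list of logical matrices (domain classes).
#' @param stimulus_classes Named list of condition-id vectors (stimulus
#'   classes; multi-condition classes are averaged per trial).
#' @param preferred Named character vector mapping each domain class to its
#'   preferred stimulus class (optional; enables significance flags).
#' @param frame_window Window for amplitudes and comparisons.
#' @return Data frame with one row per cell: `domain_class`,
#'   `stimulus_class`, `amplitude`, `sd_trials`, `n_pixels`, and (when
#'   `preferred` is given) `p_vs_preferred`.
#' @export
amplitude_summary <- function(session, domain_masks, stimulus_classes,
                              preferred = NULL, frame_window = c(9, 18)) {
  tcs <- list()
  for (dm in names(domain_masks)) {
    for (sc in names(stimulus_classes)) {
      conds <- stimulus_classes[[sc]]
      tc <- pooled_timecourse(session, conds, domain_masks[[dm]])
      tcs[[paste(dm, sc, sep = "|")]] <- tc
    }
  }
  rows <- list()
  for (dm in names(domain_masks)) {
    for (sc in names(stimulus_classes)) {
      tc <- tcs[[paste(dm, sc, sep = "|")]]
      fw <- clip_window(frame_window, nrow(tc$frames))
      win_mean <- -rowMeans(tc$trial_frames[, fw[1]:fw[2], drop = FALSE])
      p_pref <- NA_real_
      if (!is.null(preferred) && !is.na(preferred[dm]) &&
          preferred[[dm]] != sc) {
        cmp <- compare_timecourses(tcs[[paste(dm, preferred[[dm]],
                                              sep = "|")]], tc, frame_window)
        p_pref <- cmp$p_value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        domain_class = dm, stimulus_class = sc,
        amplitude = mean(win_mean), sd_trials = stats::sd(win_mean),
        n_pixels = tc$n_pixels, p_vs_preferred = p_pref)
    }
  }
  do.call(rbind, rows)
}

# Timecourse of the per-trial average over a set of conditions.
pooled_timecourse <- function(session, conds, mask) {
  tc <- NULL
  for (cid in conds) {
    one <- extract_domain_timecourse(session, cid, mask)
    if (is.null(tc)) {
      tc <- one
    } else {
      tc$frames$mean <- tc$frames$mean + one$frames$mean
      tc$trial_frames <- tc$trial_frames + one$trial_frames
    }
  }
  tc$frames$mean <- tc$frames$mean / length(conds)
  tc$trial_frames <- tc$trial_frames / length(conds)
  tc$frames$sem <- apply(tc$trial_frames, 2, stats::sd) / sqrt(tc$n_trials)
  tc$condition <- paste(conds, collapse = "+")
  tc
}
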