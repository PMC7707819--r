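# From raw frame stacks to per-trial response maps and condition-contrast
# statistic maps.  Frame labels are 1-based throughout, matching the
# convention of the imaging literature ("frames 1 to 3", "frame 8 to 16").

#' Per-frame fractional reflectance change (dR/R)
#'
#' `dR/R = (F_x - F0)/F0` per pixel, with `F0` the mean of the first
#' `n_baseline_frames` (pre-stimulus) frames.
#'
#' @param stack Reflectance array `[row, col, frame]` (one trial) or
#'   `[row, col, frame, trial]`.
#' @param n_baseline_frames Number of leading frames averaged into `F0`.
#' @return Array of the same shape: fractional change per pixel per frame.
#' @export
frame_drr <- function(stack, n_baseline_frames = 2) {
  d <- dim(stack)
  if (is.null(d) || !length(d) %in% c(3, 4))
    stop("stack must be [row, col, frame] or [row, col, frame, trial]",
         call. = FALSE)
  if (d[3] < n_baseline_frames)
    stop("stack has fewer frames than n_baseline_frames", call. = FALSE)
  if (length(d) == 4) {
    out <- stack
    for (tr in seq_len(d[4]))
      out[, , , tr] <- frame_drr(stack[, , , tr], n_baseline_frames)
    return(out)
  }
  f0 <- frame_subset_mean(stack, seq_len(n_baseline_frames))
  if (any(f0 <= 0)) {
    bad <- which(f0 <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-positive baseline at pixel (row %d, col %d): cannot form dR/R",
      bad[1], bad[2]), call. = FALSE)
  }
  sweep(sweep(stack, c(1, 2), f0, "-"), c(1, 2), f0, "/")
}

# Mean over a set of frames of a [row, col, frame] stack (fast path).
frame_subset_mean <- function(stack, frames) {
  d <- dim(stack)
  m <- stack[, , frames, drop = FALSE]
  dim(m) <- c(d[1] * d[2], length(frames))
  out <- rowMeans(m)
  dim(out) <- d[1:2]
  out
}

#' Per-trial response map
#'
#' The scalar response of each pixel in one trial:
#' `(mean of frames 8-16 - mean of frames 1-3) / (mean of frames 1-3)`
#' (1-based frame labels).
#'
#' @param stack Reflectance array `[row, col, frame]` or
#'   `[row, col, frame, trial]`.
#' @param response_frames,baseline_frames 1-based frame windows.
#' @return A matrix `[row, col]` (or array `[row, col, trial]`).
#' @export
trial_response <- function(stack, response_frames = 8:16,
                           baseline_frames = 1:3) {
  d <- dim(stack)
  if (is.null(d) || !length(d) %in% c(3, 4))
    stop("stack must be [row, col, frame] or [row, col, frame, trial]",
         call. = FALSE)
  need <- max(response_frames, baseline_frames)
  if (d[3] < need)
    stop(sprintf("stack has %d frames; frames up to %d are required",
                 d[3], need), call. = FALSE)
  if (length(d) == 4) {
    out <- array(0, dim = c(d[1], d[2], d[4]))
    for (tr in seq_len(d[4]))
      out[, , tr] <- trial_response(stack[, , , tr], response_frames,
                                    baseline_frames)
    return(out)
  }
  b <- frame_subset_mean(stack, baseline_frames)
  r <- frame_subset_mean(stack, response_frames)
  (r - b) / b
}

#' Per-trial response maps for a session condition
#'
#' @param session An [imaging_session()].
#' @param condition Condition id (or vector of ids, in which case the
#'   per-trial average across the listed conditions is returned, trials
#'   paired by index -- e.g. the per-trial average of the four straight
#'   orientations).
#' @inheritParams trial_response
#' @return Array `[row, col, trial]`.
#' @export
trial_response_maps <- function(session, condition, response_frames = 8:16,
                                baseline_frames = 1:3) {
  missing <- setdiff(condition, conditions(session))
  if (length(missing))
    stop("unknown condition(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  acc <- NULL
  for (cid in condition) {
    m <- trial_response(session$data[[cid]], response_frames, baseline_frames)
    acc <- if (is.null(acc)) m else acc + m
  }
  acc / length(condition)
}

new_response_map <- function(values, kind, contrast = NULL, roi = NULL,
                             provenance = list()) {
  structure(list(values = values, kind = kind, contrast = contrast,
                 roi = roi, provenance = provenance),
            class = "response_map")
}

#' @export
print.response_map <- function(x, ...) {
  cat("<response_map>", x$kind, paste(dim(x$values), collapse = "x"), "px")
  if (!is.null(x$contrast))
    cat("  [", paste(x$contrast$A, collapse = "+"), "vs",
        paste(x$contrast$B, collapse = "+"), "]")
  cat("\n  range:", paste(signif(range(x$values, finite = TRUE), 4),
                          collapse = " .. "), "\n")
  invisible(x)
}

#' @export
plot.response_map <- function(x, zlim = NULL, ...) {
  v <- x$values
  if (is.null(zlim)) zlim <- range(v, finite = TRUE)
  v[!is.finite(v)] <- mean(zlim)
  graphics::image(t(flip_ud(v)), col = grDevices::gray(0:255 / 255),
                  zlim = zlim, asp = nrow(v) / ncol(v), axes = FALSE, ...)
  invisible(x)
}

map_values <- function(x) if (inherits(x, "response_map")) x$values else x

#' Pixel-wise difference statistic maps (t and p)
#'
#' Per pixel, the paired t statistic
#' `t = (mean_A - mean_B) * sqrt(N) / S`, with `S` the SD of the per-trial
#' differences (conditions recorded in blocks are paired by trial index),
#' and its two-tailed p-value; or Welch's unpaired statistic.  Pixels with
#' zero difference SD get `t = +/-Inf` with `p = 0` (`t = 0`, `p = 1` when
#' the means are also equal).
#'
#' @param group_a,group_b Per-trial response arrays `[row, col, trial]`
#'   (see [trial_response_maps()]).
#' @param paired Paired (default) or Welch unpaired statistic.
#' @param scale `"sqrt_n"` (standard t statistic) or `"n"` (the literal
#'   `x N / S` display scaling used in some map figures; a monotone
#'   rescaling -- p-values are always computed from the standard statistic).
#' @return A list with `response_map` elements `t` and `p` and the degrees
#'   of freedom `df` (a matrix for Welch).
#' @export
difference_statistic_map <- function(group_a, group_b, paired = TRUE,
                                     scale = c("sqrt_n", "n")) {
  scale <- match.arg(scale)
  da <- dim(group_a); db <- dim(group_b)
  if (length(da) != 3 || length(db) != 3 || any(da[1:2] != db[1:2]))
    stop("groups must be [row, col, trial] arrays of equal pixel grid",
         call. = FALSE)
  na <- da[3]; nb <- db[3]
  if (na < 2 || nb < 2) stop("both groups need >= 2 trials", call. = FALSE)
  if (paired) {
    if (na != nb)
      stop("paired statistic requires equal trial counts", call. = FALSE)
    d <- group_a - group_b
    m <- rowMeans(d, dims = 2)
    s2 <- (rowSums(d^2, dims = 2) - na * m^2) / (na - 1)
    s2[s2 < 0] <- 0
    s <- sqrt(s2)
    tval <- m * sqrt(na) / s
    tval[s == 0 & m == 0] <- 0
    df <- na - 1
    pval <- 2 * stats::pt(-abs(tval), df)
    pval[is.infinite(tval)] <- 0
    tout <- if (scale == "n") m * na / s else tval
    tout[s == 0 & m == 0] <- 0
  } else {
    ma <- rowMeans(group_a, dims = 2)
    mb <- rowMeans(group_b, dims = 2)
    va <- (rowSums(group_a^2, dims = 2) - na * ma^2) / (na - 1)
    vb <- (rowSums(group_b^2, dims = 2) - nb * mb^2) / (nb - 1)
    va[va < 0] <- 0; vb[vb < 0] <- 0
    se2 <- va / na + vb / nb
    tval <- (ma - mb) / sqrt(se2)
    tval[se2 == 0 & ma == mb] <- 0
    df <- se2^2 / (va^2 / (na^2 * (na - 1)) + vb^2 / (nb^2 * (nb - 1)))
    pval <- 2 * stats::pt(-abs(tval), df)
    pval[is.infinite(tval)] <- 0
    pval[tval == 0 & se2 == 0] <- 1
    tout <- tval
  }
  pval[tval == 0] <- 1
  list(t = new_response_map(tout, "t_value"),
       p = new_response_map(pval, "p_value"),
       df = df)
}

#' Band-pass spatial filtering of a map
#'
#' The standard two-scale filtering of intrinsic-signal maps: Gaussian
#' smoothing at the domain scale (default 10 px diameter, read as FWHM, so
#' `sigma = diameter/2.355`) minus a circular (disc) mean at the
#' low-frequency scale (default 120 px diameter, within the field's
#' 100-150 px range), which removes global illumination/drift structure.
#' `NA` pixels are mean-imputed before filtering and restored after.
#'
#' @param map A matrix or `response_map`.
#' @param smooth_diameter_px Gaussian FWHM, pixels.
#' @param lowfreq_diameter_px Disc diameter for the subtracted low-frequency
#'   component, pixels; must exceed `smooth_diameter_px`.
#' @return Same type as the input, filtered.
#' @export
filter_map <- function(map, smooth_diameter_px = 10,
                       lowfreq_diameter_px = 120) {
  if (smooth_diameter_px < 1 || lowfreq_diameter_px <= smooth_diameter_px)
    stop("need lowfreq_diameter_px > smooth_diameter_px >= 1", call. = FALSE)
  v <- map_values(map)
  nas <- !is.finite(v)
  if (any(nas)) v[nas] <- mean(v[!nas])
  out <- gaussian_filter(v, smooth_diameter_px / 2.355) -
    disc_mean_filter(v, lowfreq_diameter_px)
  out[nas] <- NA_real_
  if (inherits(map, "response_map")) {
    map$values <- out
    map$provenance$filtered <- c(smooth_diameter_px, lowfreq_diameter_px)
    map
  } else out
}

#' Condition-contrast statistic maps from a session
#'
#' The work-horse of map making: per-trial response maps are formed for the
#' two condition sets (each set averaged per trial, trials paired by index),
#' spatially filtered per trial ([filter_map()]), and compared with the
#' paired t statistic.  Filtering before the statistic leaves the mean
#' difference map identical (the filters are linear) while keeping the
#' per-pixel null distribution exactly Student-t; `filter_trials = FALSE`
#' instead filters the mean difference map only, reproducing the literal
#' map-then-filter ordering.
#'
#' @param session An [imaging_session()].
#' @param conditions_a,conditions_b Condition id sets (A vs B).
#' @param filter_trials Filter each per-trial map before the statistic.
#' @param smooth_diameter_px,lowfreq_diameter_px See [filter_map()].
#' @param paired,scale See [difference_statistic_map()].
#' @return A list with `response_map`s `t`, `p` and `diff` (the mean
#'   filtered dR/R difference), plus `df`.
#' @export
contrast_map <- function(session, conditions_a, conditions_b,
                         filter_trials = TRUE,
                         smooth_diameter_px = 10, lowfreq_diameter_px = 120,
                         paired = TRUE, scale = "sqrt_n") {
  a <- trial_response_maps(session, conditions_a)
  b <- trial_response_maps(session, conditions_b)
  if (filter_trials) {
    for (tr in seq_len(dim(a)[3]))
      a[, , tr] <- filter_map(a[, , tr], smooth_diameter_px,
                              lowfreq_diameter_px)
    for (tr in seq_len(dim(b)[3]))
      b[, , tr] <- filter_map(b[, , tr], smooth_diameter_px,
                              lowfreq_diameter_px)
  }
  res <- difference_statistic_map(a, b, paired = paired, scale = scale)
  diffmap <- rowMeans(a, dims = 2) - rowMeans(b, dims = 2)
  if (!filter_trials)
    diffmap <- filter_map(diffmap, smooth_diameter_px, lowfreq_diameter_px)
  contrast <- list(A = conditions_a, B = conditions_b)
  res$t$contrast <- contrast; res$p$contrast <- contrast
  res$diff <- new_response_map(diffmap, "drr_diff", contrast)
  res
}

#' Single-condition map
#'
#' Contrast of one condition against the per-trial average of the straight
#' gratings (conventionally the four orientations 0, 45, 90, 135 degrees).
#'
#' @param session An [imaging_session()].
#' @param condition Condition id.
#' @param straight_set Ids of the straight-grating reference conditions.
#' @param ... Passed to [contrast_map()].
#' @return As [contrast_map()].
#' @export
single_condition_map <- function(session, condition, straight_set, ...) {
  if (length(straight_set) < 1)
    stop("straight_set must be nonempty", call. = FALSE)
  contrast_map(session, condition, straight_set, ...)
}
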