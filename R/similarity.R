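# Map-similarity analysis: ROI-restricted cross-correlation matrices and
# the relation between response similarity and curvature-degree difference.

#' ROI of curvature-responsive cortex
#'
#' Union of pixels significantly activated (negative contrast, `p < alpha`)
#' versus blank across the given curvature conditions -- the region of the
#' imaged field that curvature stimuli can drive.
#'
#' @param session An [imaging_session()].
#' @param curvature_conditions Condition ids of the curvature battery.
#' @param blank_condition Blank condition id.
#' @param alpha Per-pixel significance level.
#' @param ... Passed to [contrast_map()].
#' @return Logical matrix.
#' @export
curvature_roi <- function(session, curvature_conditions, blank_condition,
                          alpha = 0.01, ...) {
  roi <- NULL
  for (cid in curvature_conditions) {
    cm <- contrast_map(session, cid, blank_condition, ...)
    m <- cm$p$values < alpha & cm$t$values < 0
    roi <- if (is.null(roi)) m else roi | m
  }
  roi
}

#' Pearson correlation between two maps over an ROI
#'
#' @param map_a,map_b Matrices or `response_map`s of equal shape.
#' @param roi Logical matrix; `NULL` uses all finite pixels.
#' @return Correlation coefficient; `NA` (with a warning) when either map
#'   has zero variance over the ROI.
#' @export
map_correlation <- function(map_a, map_b, roi = NULL) {
  a <- map_values(map_a); b <- map_values(map_b)
  if (!all(dim(a) == dim(b)))
    stop("maps must share shape", call. = FALSE)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(a), ncol(a))
  sel <- roi & is.finite(a) & is.finite(b)
  if (!any(sel)) stop("ROI is empty", call. = FALSE)
  x <- a[sel]; y <- b[sel]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance over ROI; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Pairwise correlation matrix of condition maps
#'
#' @param maps Named list of matrices or `response_map`s (e.g. filtered
#'   single-condition maps).
#' @param roi Logical ROI mask (see [curvature_roi()]); `NULL` uses all
#'   pixels.
#' @param labels Optional data.frame of condition attributes (one row per
#'   map, e.g. curvature ratio and orientation), carried in the result.
#' @return Object of class `correlation_matrix`: the K x K symmetric
#'   matrix (unit diagonal), plus `labels` and the ROI.
#' @export
correlation_matrix <- function(maps, roi = NULL, labels = NULL) {
  k <- length(maps)
  if (k < 2) stop("need >= 2 maps", call. = FALSE)
  nm <- names(maps)
  if (is.null(nm)) nm <- paste0("map", seq_len(k))
  vals <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    vals[i, i] <- 1
    for (j in seq_len(k)[-seq_len(i)]) {
      r <- suppressWarnings(map_correlation(maps[[i]], maps[[j]], roi))
      vals[i, j] <- r
      vals[j, i] <- r
    }
  }
  structure(list(values = vals, labels = labels, roi = roi),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("<correlation_matrix>", nrow(x$values), "conditions\n")
  print(round(x$values, digits))
  invisible(x)
}

#' Correlation versus curvature-degree difference
#'
#' For each reference condition, regresses the correlation of its map with
#' every other map against the absolute difference of curvature-degree
#' *ranks* (the condition number stands in for relative curvature degree),
#' and pools a common slope across references.  A negative slope is the
#' signature of a spatially progressing degree representation: the more
#' similar the curvature, the greater the correlation.
#'
#' @param cmat A [correlation_matrix()].
#' @param degree_index Numeric vector of ordinal degree ranks, one per
#'   condition (row of the matrix).
#' @param min_points References with fewer points are flagged and excluded
#'   from pooling.
#' @return List with `per_reference` (data.frame: reference, slope,
#'   intercept, r_squared, n, used) and `pooled` (slope, intercept,
#'   r_squared over all unordered pairs).
#' @export
degree_difference_regression <- function(cmat, degree_index,
                                         min_points = 3) {
  v <- cmat$values
  k <- nrow(v)
  if (length(degree_index) != k)
    stop("degree_index must have one rank per condition", call. = FALSE)
  per <- lapply(seq_len(k), function(i) {
    j <- setdiff(seq_len(k), i)
    dd <- abs(degree_index[j] - degree_index[i])
    rr <- v[i, j]
    ok <- is.finite(rr)
    used <- sum(ok) >= min_points && length(unique(dd[ok])) >= 2
    if (used) {
      fit <- stats::lm(rr[ok] ~ dd[ok])
      data.frame(reference = rownames(v)[i],
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = lm_r_squared(fit, rr[ok]),
                 n = sum(ok), used = TRUE)
    } else {
      data.frame(reference = rownames(v)[i], slope = NA_real_,
                 intercept = NA_real_, r_squared = NA_real_,
                 n = sum(ok), used = FALSE)
    }
  })
  per <- do.call(rbind, per)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  dd <- abs(degree_index[ut[, 1]] - degree_index[ut[, 2]])
  rr <- v[upper.tri(v)]
  ok <- is.finite(rr)
  pooled_fit <- stats::lm(rr[ok] ~ dd[ok])
  list(per_reference = per,
       pooled = list(slope = unname(coef(pooled_fit)[2]),
                     intercept = unname(coef(pooled_fit)[1]),
                     r_squared = lm_r_squared(pooled_fit, rr[ok]),
                     n = sum(ok)))
}

# R^2 without summary.lm (whose perfect-fit warning is unhelpful here).
lm_r_squared <- function(fit, y) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / sst
}
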