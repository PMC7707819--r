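# Straight-to-curved domain progressions: starting from a straight
# orientation domain, link the nearest curvature domain of each curvature
# degree and measure centroid distances as a function of degree.

#' Link a straight domain to the nearest curvature domain per ratio
#'
#' For each curvature ratio, selects from that ratio's domain set the
#' domain whose activation centre is nearest (Euclidean, in cortical mm) to
#' the straight domain's centre; ties break to the lower domain id.
#' Orientation congruence is the caller's responsibility: pass domain sets
#' restricted to the matching curve-orientation class.
#'
#' @param straight_centroid_mm `c(row, col)` centre of the straight
#'   orientation domain, mm (e.g. from a `domain_set` row).
#' @param domain_sets_by_ratio Named list `ratio -> domain_set` (names are
#'   the curvature ratios, increasing).
#' @param orientation Optional label recorded in the result.
#' @return Object of class `progression_record`: the straight centroid and
#'   a data.frame `steps` with `ratio`, `domain_id`, `centroid_row_mm`,
#'   `centroid_col_mm`, `distance_mm` (NA rows flag ratios whose domain set
#'   was empty).
#' @export
nearest_curvature_domains <- function(straight_centroid_mm,
                                      domain_sets_by_ratio,
                                      orientation = NA_character_) {
  ratios <- as.numeric(names(domain_sets_by_ratio))
  if (any(is.na(ratios)))
    stop("domain_sets_by_ratio must be named by numeric ratio", call. = FALSE)
  if (is.unsorted(ratios, strictly = TRUE))
    stop("ratios must be strictly increasing", call. = FALSE)
  steps <- lapply(seq_along(ratios), function(i) {
    ds <- domain_sets_by_ratio[[i]]
    if (nrow(ds$domains) == 0) {
      return(data.frame(ratio = ratios[i], domain_id = NA_integer_,
                        centroid_row_mm = NA_real_,
                        centroid_col_mm = NA_real_, distance_mm = NA_real_))
    }
    d <- sqrt((ds$domains$centroid_row_mm - straight_centroid_mm[1])^2 +
                (ds$domains$centroid_col_mm - straight_centroid_mm[2])^2)
    best <- which(d == min(d))
    best <- best[which.min(ds$domains$id[best])]
    data.frame(ratio = ratios[i], domain_id = ds$domains$id[best],
               centroid_row_mm = ds$domains$centroid_row_mm[best],
               centroid_col_mm = ds$domains$centroid_col_mm[best],
               distance_mm = d[best])
  })
  steps <- do.call(rbind, steps)
  if (all(is.na(steps$distance_mm)))
    stop("all ratios have empty domain sets", call. = FALSE)
  structure(list(straight_centroid_mm = straight_centroid_mm,
                 orientation = orientation,
                 steps = steps),
            class = "progression_record")
}

#' @export
print.progression_record <- function(x, ...) {
  cat("<progression_record> straight centre at (",
      paste(signif(x$straight_centroid_mm, 4), collapse = ", "), ") mm\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Centroid distances and monotonicity of a progression
#'
#' Euclidean distances from the straight domain centre to each linked
#' curvature domain centre, with the Spearman rank correlation of distance
#' against curvature ratio.  A progression is flagged `shifting` when the
#' correlation exceeds `shift_threshold` -- a reporting convenience for
#' "parts of these sequences shift and others do not", not an inferential
#' statistic.
#'
#' @param record A `progression_record`.
#' @param shift_threshold Spearman correlation above which the record is
#'   flagged shifting.
#' @return List with `distances_mm` (named by ratio), `spearman`,
#'   `shifting`, and `mean_spacing_mm` (mean increment of distance between
#'   consecutive present ratios).
#' @export
progression_distances <- function(record, shift_threshold = 0.5) {
  st <- record$steps[!is.na(record$steps$distance_mm), ]
  if (nrow(st) < 2)
    stop("need >= 2 ratios with domains present", call. = FALSE)
  d <- stats::setNames(st$distance_mm, st$ratio)
  rho <- if (stats::sd(d) == 0) 0 else
    suppressWarnings(stats::cor(st$ratio, st$distance_mm,
                                method = "spearman"))
  list(distances_mm = d,
       spearman = rho,
       shifting = is.finite(rho) && rho > shift_threshold,
       mean_spacing_mm = mean(diff(st$distance_mm)))
}

#' Average progression distance per ratio
#'
#' Mean and sample SD of centroid distance per curvature ratio over a set
#' of progression records (missing ratios excluded pairwise).
#'
#' @param records List of `progression_record`s.
#' @return Data frame with `ratio`, `mean_distance_mm`, `sd_distance_mm`
#'   (sample SD; 0 for a single record), `n`.
#' @export
average_progression <- function(records) {
  if (length(records) < 1) stop("need >= 1 record", call. = FALSE)
  steps <- do.call(rbind, lapply(records, `[[`, "steps"))
  steps <- steps[!is.na(steps$distance_mm), ]
  agg <- stats::aggregate(distance_mm ~ ratio, steps, function(x)
    c(mean = mean(x), sd = if (length(x) > 1) stats::sd(x) else 0,
      n = length(x)))
  out <- data.frame(ratio = agg$ratio,
                    mean_distance_mm = agg$distance_mm[, "mean"],
                    sd_distance_mm = agg$distance_mm[, "sd"],
                    n = as.integer(agg$distance_mm[, "n"]))
  out[order(out$ratio), ]
}
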