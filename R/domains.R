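# Significant-domain detection, morphometrics and overlap quantification.

# Connected-component labeling by iterative minimum-label propagation.
# EBImage::bwlabel is 4-connected only; domain analysis conventionally uses
# 8-connectivity, so labeling is done here with a connectivity flag.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lbl <- matrix(0L, nr, nc)
  lbl[mask] <- seq_len(sum(mask))
  if (sum(mask) == 0) return(lbl)
  big <- nr * nc + 1L
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  if (connectivity == 8)
    shifts <- c(shifts, list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)))
  repeat {
    cur <- ifelse(mask, lbl, big)
    best <- cur
    for (s in shifts) {
      sh <- matrix(big, nr, nc)
      rs <- seq_len(nr) - s[1]; cs <- seq_len(nc) - s[2]
      ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
      sh[ok_r, ok_c] <- cur[rs[ok_r], cs[ok_c]]
      best <- pmin(best, sh)
    }
    best[!mask] <- big
    if (all(best[mask] == lbl[mask])) break
    lbl[mask] <- best[mask]
  }
  compact_labels(lbl)
}

compact_labels <- function(lbl) {
  ids <- sort(unique(lbl[lbl > 0]))
  if (length(ids) == 0) return(lbl)
  lbl[lbl > 0] <- match(lbl[lbl > 0], ids)
  lbl
}

#' Morphometrics of one patch
#'
#' Fits the patch's second-moment (inertia) ellipse; `R` is the mean of its
#' semi-axes, the patch size is `pi * R^2`, the equivalent diameter `2R`,
#' and the activation centre is the unweighted pixel centre of mass.
#' Physical coordinates are mm from the top-left pixel centre.
#'
#' @param mask Logical matrix selecting the patch pixels (nonempty).
#' @param pixel_size_mm Pixel pitch, mm.
#' @return List with `area_mm2` (`pi*R^2`), `equivalent_diameter_mm` (`2R`),
#'   `centroid_mm` (`c(row, col)`), `semi_axes_mm` (major, minor),
#'   `n_pixels` and `pixel_area_mm2` (pixel count times pixel area).
#' @export
domain_morphometry <- function(mask, pixel_size_mm) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0) stop("empty patch mask", call. = FALSE)
  xy <- (idx - 1) * pixel_size_mm
  ctr <- colMeans(xy)
  if (n == 1) {
    semi <- c(0, 0)
  } else {
    cc <- stats::cov(xy) * (n - 1) / n # population second moments
    ev <- eigen(cc, symmetric = TRUE)$values
    ev[ev < 0] <- 0
    semi <- 2 * sqrt(ev) # uniform-disk convention: semi-axis = 2*sd
  }
  r <- mean(semi)
  list(area_mm2 = pi * r^2,
       equivalent_diameter_mm = 2 * r,
       centroid_mm = unname(ctr),
       semi_axes_mm = semi,
       n_pixels = n,
       pixel_area_mm2 = n * pixel_size_mm^2)
}

#' Construct a domain set from a label image
#'
#' Computes per-domain morphometrics ([domain_morphometry()]) for an
#' existing integer label image (0 = background), e.g. planted ground-truth
#' patches or externally segmented domains.
#'
#' @param label_image Integer matrix; labels need not be contiguous.
#' @param pixel_size_mm Pixel pitch, mm.
#' @param t_map Optional statistic map for per-domain mean t.
#' @return A `domain_set`.
#' @export
domain_set <- function(label_image, pixel_size_mm, t_map = NULL) {
  lbl <- compact_labels(label_image)
  domains_table(lbl, if (is.null(t_map)) NULL else map_values(t_map),
                pixel_size_mm, contrast = NULL, sign = NULL)
}

new_domain_set <- function(label_image, domains, pixel_size_mm,
                           contrast = NULL, sign = NULL) {
  structure(list(label_image = label_image, domains = domains,
                 pixel_size_mm = pixel_size_mm, contrast = contrast,
                 sign = sign),
            class = "domain_set")
}

#' @export
print.domain_set <- function(x, ...) {
  cat("<domain_set>", nrow(x$domains), "domains over",
      paste(dim(x$label_image), collapse = "x"), "px\n")
  if (nrow(x$domains) > 0) {
    cat("  equivalent diameters (mm):",
        paste(signif(sort(x$domains$eq_diam_mm), 3), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.domain_set <- function(x, ...) {
  k <- max(x$label_image)
  cols <- c("black", grDevices::hsv(seq(0, 0.9, length.out = max(k, 1)),
                                    0.8, 0.95))
  graphics::image(t(flip_ud(x$label_image)), col = cols, axes = FALSE,
                  asp = nrow(x$label_image) / ncol(x$label_image), ...)
  invisible(x)
}

domains_table <- function(label_image, tmap, pixel_size_mm, contrast, sign) {
  k <- max(label_image)
  if (k == 0) {
    return(new_domain_set(label_image,
                          data.frame(id = integer(0), area_mm2 = numeric(0),
                                     eq_diam_mm = numeric(0),
                                     centroid_row_mm = numeric(0),
                                     centroid_col_mm = numeric(0),
                                     n_pixels = integer(0),
                                     mean_t = numeric(0)),
                          pixel_size_mm, contrast, sign))
  }
  rows <- lapply(seq_len(k), function(i) {
    m <- label_image == i
    mm <- domain_morphometry(m, pixel_size_mm)
    data.frame(id = i, area_mm2 = mm$area_mm2,
               eq_diam_mm = mm$equivalent_diameter_mm,
               centroid_row_mm = mm$centroid_mm[1],
               centroid_col_mm = mm$centroid_mm[2],
               n_pixels = mm$n_pixels,
               mean_t = if (is.null(tmap)) NA_real_ else
                 mean(tmap[m][is.finite(tmap[m])]))
  })
  new_domain_set(label_image, do.call(rbind, rows), pixel_size_mm,
                 contrast, sign)
}

#' Detect significant functional domains
#'
#' Keeps pixels with `p < alpha` whose statistic has the requested sign
#' (`"negative"` selects activation under the intrinsic-signal convention:
#' preferred conditions darken the image), optionally applies a second
#' one-way ANOVA + Tukey-Kramer gate across condition groups, labels
#' connected components, and computes per-domain morphometrics.
#'
#' @param t_map,p_map Matrices or `response_map`s of the contrast statistic
#'   (see [contrast_map()]).
#' @param sign `"negative"` or `"positive"`.
#' @param alpha Per-pixel significance level (the field convention is an
#'   uncorrected 0.01; set `adjust = "BH"` for Benjamini-Hochberg).
#' @param anova_groups Optional named list with elements `a` and `b`, each a
#'   list of `[row, col, trial]` per-trial response arrays (one per
#'   condition).  Candidate pixels must additionally pass one-way ANOVA
#'   across all conditions at `anova_alpha` with at least one (`rule =
#'   "any"`) or all (`rule = "all"`) Tukey-corrected a-vs-b pairwise
#'   comparisons significant in the requested direction.
#' @param anova_alpha Significance level for the ANOVA gate.
#' @param rule Tukey pairwise rule, `"any"` or `"all"`.
#' @param adjust `"none"` (default) or `"BH"` multiplicity adjustment of the
#'   p map before thresholding.
#' @param connectivity 8 (default) or 4.
#' @param pixel_size_mm Pixel pitch, mm.
#' @return A `domain_set`; empty input yields a valid empty set.
#' @export
detect_domains <- function(t_map, p_map, sign = c("negative", "positive"),
                           alpha = 0.01, anova_groups = NULL,
                           anova_alpha = 0.05, rule = c("any", "all"),
                           adjust = c("none", "BH"),
                           connectivity = 8, pixel_size_mm = 1) {
  sign <- match.arg(sign); rule <- match.arg(rule)
  adjust <- match.arg(adjust)
  tv <- map_values(t_map); pv <- map_values(p_map)
  if (!all(dim(tv) == dim(pv)))
    stop("t and p maps must share shape", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  if (adjust == "BH") {
    pv <- matrix(stats::p.adjust(pv, "BH"), nrow(pv), ncol(pv))
  }
  mask <- is.finite(pv) & pv < alpha &
    (if (sign == "negative") tv < 0 else tv > 0)
  if (!is.null(anova_groups) && any(mask)) {
    gate <- anova_tukey_gate(anova_groups$a, anova_groups$b, mask,
                             anova_alpha, sign, rule)
    mask <- mask & gate
  }
  lbl <- label_components(mask, connectivity)
  contrast <- if (inherits(t_map, "response_map")) t_map$contrast else NULL
  domains_table(lbl, tv, pixel_size_mm, contrast, sign)
}

# Vectorised one-way ANOVA + Tukey-Kramer across condition groups,
# evaluated at masked pixels only.  groups_a / groups_b: lists of
# [row, col, trial] arrays.  A pixel passes when the omnibus ANOVA is
# significant and the Tukey-corrected a-vs-b pairwise comparisons go in the
# requested direction.
anova_tukey_gate <- function(groups_a, groups_b, mask, alpha, sign, rule) {
  groups <- c(groups_a, groups_b)
  k <- length(groups)
  ia <- seq_along(groups_a)
  ib <- length(groups_a) + seq_along(groups_b)
  idx <- which(mask)
  ns <- vapply(groups, function(g) dim(g)[3], 1L)
  n_tot <- sum(ns)
  means <- lapply(groups, function(g) {
    m <- rowMeans(g, dims = 2)
    m[idx]
  })
  ssw <- 0
  for (j in seq_len(k)) {
    g <- groups[[j]]
    d <- dim(g)
    gm <- matrix(g, d[1] * d[2], d[3])[idx, , drop = FALSE]
    ssw <- ssw + rowSums((gm - means[[j]])^2)
  }
  grand <- Reduce(`+`, Map(`*`, means, ns)) / n_tot
  ssb <- Reduce(`+`, Map(function(m, n) n * (m - grand)^2, means, ns))
  df1 <- k - 1; df2 <- n_tot - k
  msw <- ssw / df2
  fstat <- (ssb / df1) / msw
  p_f <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  pass <- p_f < alpha
  pair_ok <- if (rule == "any") rep(FALSE, length(idx)) else
    rep(TRUE, length(idx))
  for (a in ia) for (b in ib) {
    diff <- means[[a]] - means[[b]]
    se <- sqrt(msw / 2 * (1 / ns[a] + 1 / ns[b]))
    q <- abs(diff) / se
    p_q <- stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    good_dir <- if (sign == "negative") diff < 0 else diff > 0
    sig <- p_q < alpha & good_dir
    pair_ok <- if (rule == "any") pair_ok | sig else pair_ok & sig
  }
  gate <- matrix(FALSE, nrow(mask), ncol(mask))
  gate[idx] <- pass & pair_ok
  gate
}

#' Remove small patches from a domain set
#'
#' Domains with equivalent diameter below `min_diameter_mm` (field
#' convention: 0.2 mm, below which patch reliability is poor) are removed
#' and the labels recompacted.
#'
#' @param domain_set A `domain_set`.
#' @param min_diameter_mm Minimum equivalent diameter, mm.
#' @return The filtered `domain_set`.
#' @export
filter_small_patches <- function(domain_set, min_diameter_mm = 0.2) {
  keep <- domain_set$domains$eq_diam_mm >= min_diameter_mm
  lbl <- domain_set$label_image
  lbl[!(lbl %in% domain_set$domains$id[keep])] <- 0L
  lbl <- compact_labels(lbl)
  dom <- domain_set$domains[keep, , drop = FALSE]
  if (nrow(dom) > 0) dom$id <- seq_len(nrow(dom))
  rownames(dom) <- NULL
  new_domain_set(lbl, dom, domain_set$pixel_size_mm, domain_set$contrast,
                 domain_set$sign)
}

#' Overlap percentage of two pixel masks
#'
#' `100 * |A intersect B| / |A union B|` (intersection over union), the
#' headline quantification of how much two domain classes share territory
#' ("overlapped pixels vs. all colored pixels").  `mode = "min"` reports the
#' intersection against the smaller mask instead.
#'
#' @param mask_a,mask_b Logical matrices of equal shape.
#' @param mode `"union"` (IoU, default; `"colored"` is an alias) or
#'   `"min"`.
#' @return Percentage in `[0, 100]`; two empty masks give 0 with a warning
#'   and attribute `empty = TRUE`.
#' @export
overlap_percentage <- function(mask_a, mask_b,
                               mode = c("union", "colored", "min")) {
  mode <- match.arg(mode)
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("masks must share shape", call. = FALSE)
  inter <- sum(mask_a & mask_b)
  uni <- sum(mask_a | mask_b)
  if (uni == 0) {
    warning("both masks are empty; overlap undefined, returning 0")
    return(structure(0, empty = TRUE))
  }
  denom <- if (mode == "min") min(sum(mask_a), sum(mask_b)) else uni
  100 * inter / denom
}

#' Dice coefficient of two masks
#'
#' `2|A n B| / (|A| + |B|)`; the standard agreement score for
#' detected-vs-planted domain masks.
#'
#' @param mask_a,mask_b Logical matrices of equal shape.
#' @return Dice coefficient in `[0, 1]` (1 when both masks are empty).
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b)))
    stop("masks must share shape", call. = FALSE)
  s <- sum(mask_a) + sum(mask_b)
  if (s == 0) return(1)
  2 * sum(mask_a & mask_b) / s
}
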