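# Synthetic cortical architecture: ground-truth per-pixel tuning maps used
# by the imaging simulator and by parameter-recovery tests.
#
# The generated architecture mirrors the organisation reported for macaque
# V4 at the sub-millimetre scale: alternating colour/orientation bands, a
# smooth 180-periodic orientation preference map containing pinwheels,
# compact curvature-preferring domains (200-500 um equivalent diameter)
# planted inside orientation bands, and optional linear straight-to-curved
# centroid progressions of increasing preferred curvature degree.

#' Generate a synthetic cortical model
#'
#' Builds the per-pixel ground truth consumed by [simulate_session()]:
#' an orientation preference angle map (band-pass filtered complex white
#' noise, half-angle; its singularities are the planted pinwheels), a
#' colour/orientation band parcellation, a spatial-frequency preference
#' parcellation, curvature domains with preferred curvature degree and
#' curve orientation, a per-pixel peak-response amplitude map, and
#' (optionally) linear centroid progressions of increasing curvature degree
#' anchored at straight-orientation domains.
#'
#' @param n_rows,n_cols Grid size in pixels (>= 64).
#' @param pixel_size_mm Cortical pixel pitch, mm/pixel.
#' @param map_wavelength_mm Characteristic wavelength of the orientation
#'   map (hypercolumn spacing), mm.
#' @param band_period_mm Period of the colour/orientation band alternation,
#'   mm.
#' @param orientation_band_fraction Fraction of cortex assigned to
#'   orientation (achromatic) bands.
#' @param n_domains Number of independently placed curvature domains
#'   (ignored for the pixels claimed by progressions).
#' @param domain_diameter_mm Range (min, max) of planted curvature-domain
#'   equivalent diameters, mm.
#' @param ratios Curvature ratios sampled for independently placed domains.
#' @param curve_orientations Apex directions sampled for planted domains.
#' @param progressions Optional list describing planted straight-to-curved
#'   progressions, with elements `n` (number of progressions), `spacing_mm`
#'   (centroid spacing between consecutive ratios), `ratios` (increasing
#'   curvature ratios) and optionally `diameter_mm` (domain diameter used
#'   for progression domains, default 0.35).
#' @param amplitude_range Range of per-pixel peak |dR/R| response amplitudes
#'   (fraction units); the field default 1e-4..3e-4 corresponds to the
#'   0.01-0.03 percent amplitudes typical of intrinsic signals.
#' @param degree_sigma Tuning width (SD) of the curvature-degree Gaussian on
#'   the log(1 + ratio) axis; the default gives the graded responses across
#'   neighbouring degrees seen in degree batteries.
#' @param straight_gain Relative response of curvature-domain pixels to
#'   straight contours (the field observes roughly an order of magnitude
#'   less than the curved optimum).
#' @param orientation_kappa Concentration of the 180-periodic straight
#'   orientation von Mises tuning term.
#' @param curve_orientation_kappa Concentration of the 360-periodic curve
#'   orientation von Mises tuning term.
#' @param scramble_gain Relative, untuned response to scrambled gratings.
#' @param min_separation_mm Minimum edge-to-edge separation enforced
#'   between independently placed domains (members of one progression may
#'   abut or overlap, as progression domains do in cortex).
#' @param seed Integer seed; the model is deterministic given the seed.
#' @return An object of class `cortical_model`: a list with per-pixel maps
#'   (`orientation_angle_map`, `orientation_magnitude_map`, `band_map`,
#'   `sf_pref_map`, `curvature_domain_mask`, `curvature_ratio_pref_map`,
#'   `curvature_orient_pref_map`, `curve_orientation_kappa_map`,
#'   `amplitude_map`, `domain_profile`), the planted-domain table
#'   (`domains`), `planted_progressions`, `pinwheel_centers`, and the tuning
#'   hyper-parameters.
#' @export
make_cortical_model <- function(n_rows = 256, n_cols = 256,
                                pixel_size_mm = 0.01,
                                map_wavelength_mm = 0.7,
                                band_period_mm = 1.7,
                                orientation_band_fraction = 0.6,
                                n_domains = 8,
                                domain_diameter_mm = c(0.2, 0.5),
                                ratios = c(2, 5),
                                curve_orientations = c("up", "down",
                                                       "left", "right"),
                                progressions = NULL,
                                amplitude_range = c(1e-4, 3e-4),
                                degree_sigma = 0.8,
                                straight_gain = 0.1,
                                orientation_kappa = 2,
                                curve_orientation_kappa = 1,
                                scramble_gain = 0.3,
                                min_separation_mm = 0.1,
                                seed = 1L) {
  if (n_rows < 64 || n_cols < 64)
    stop("grid must be at least 64x64 pixels", call. = FALSE)
  stopifnot_scalar_pos(pixel_size_mm, "pixel_size_mm")
  with_seed(seed, {
    ori <- orientation_map_field(n_rows, n_cols,
                                 map_wavelength_mm / pixel_size_mm)
    band <- band_parcellation(n_rows, n_cols,
                              band_period_mm / pixel_size_mm,
                              orientation_band_fraction)
    sfp <- smooth_noise_field(n_rows, n_cols,
                              0.5 * map_wavelength_mm / pixel_size_mm)
    sf_pref <- ifelse(sfp > 0, "high", "low")
    dim(sf_pref) <- c(n_rows, n_cols)

    amp <- smooth_noise_field(n_rows, n_cols, 8)
    amp <- mean(amplitude_range) + diff(amplitude_range) / 2 * amp
    amp <- pmin(pmax(amp, amplitude_range[1]), amplitude_range[2])

    placed <- plant_domains(n_rows, n_cols, pixel_size_mm, band,
                            n_domains, domain_diameter_mm, ratios,
                            curve_orientations, progressions,
                            min_separation_mm)

    kappa_map <- matrix(curve_orientation_kappa, n_rows, n_cols)

    model <- structure(list(
      n_rows = n_rows, n_cols = n_cols, pixel_size_mm = pixel_size_mm,
      orientation_angle_map = ori$angle,
      orientation_magnitude_map = ori$magnitude,
      band_map = band,
      sf_pref_map = sf_pref,
      curvature_domain_mask = placed$mask,
      curvature_ratio_pref_map = placed$ratio_pref,
      curvature_orient_pref_map = placed$orient_pref,
      curve_orientation_kappa_map = kappa_map,
      amplitude_map = amp,
      domain_profile = placed$profile,
      domains = placed$domains,
      planted_progressions = placed$progressions,
      pinwheel_centers = NULL,
      degree_sigma = degree_sigma,
      straight_gain = straight_gain,
      orientation_kappa = orientation_kappa,
      curve_orientation_kappa = curve_orientation_kappa,
      scramble_gain = scramble_gain,
      seed = as.integer(seed)), class = "cortical_model")
    model$pinwheel_centers <- plaquette_pinwheels(ori$angle)
    model
  })
}

#' @export
print.cortical_model <- function(x, ...) {
  cat("<cortical_model>", x$n_rows, "x", x$n_cols, "px at",
      x$pixel_size_mm, "mm/px (",
      round(x$n_rows * x$pixel_size_mm, 2), "x",
      round(x$n_cols * x$pixel_size_mm, 2), "mm )\n")
  cat("  curvature domains:", nrow(x$domains),
      " progressions:", length(x$planted_progressions),
      " pinwheels:", nrow(x$pinwheel_centers), "\n")
  cat("  orientation-band fraction:",
      round(mean(x$band_map == "orientation"), 2), "\n")
  invisible(x)
}

# Orientation preference map: annular band-pass filtered complex Gaussian
# white noise; preferred angle is the half-argument (180-periodic), so the
# zeros of the complex field are pinwheels.
orientation_map_field <- function(n_rows, n_cols, wavelength_px) {
  z <- matrix(complex(real = stats::rnorm(n_rows * n_cols),
                      imaginary = stats::rnorm(n_rows * n_cols)),
              n_rows, n_cols)
  fft_freq <- function(n) {
    i <- seq_len(n) - 1L
    ifelse(i <= n %/% 2, i, i - n) / n
  }
  k <- sqrt(outer(fft_freq(n_rows)^2, fft_freq(n_cols)^2, "+"))
  k0 <- 1 / wavelength_px
  ring <- exp(-((k - k0) / (0.35 * k0))^2)
  zf <- stats::fft(stats::fft(z) * ring, inverse = TRUE)
  angle <- (Arg(zf) * 90 / pi) %% 180
  mag <- Mod(zf) / max(Mod(zf))
  list(angle = angle, magnitude = mag)
}

# Alternating colour/orientation bands: smoothed oblique stripes with a
# slight meander, thresholded at the requested orientation-band fraction.
band_parcellation <- function(n_rows, n_cols, period_px, ori_fraction) {
  x <- outer(rep(1, n_rows), seq_len(n_cols))
  y <- outer(seq_len(n_rows), rep(1, n_cols))
  wobble <- smooth_noise_field(n_rows, n_cols, period_px / 4) * period_px / 6
  s <- sin(2 * pi * (0.94 * x + 0.34 * y + wobble) / period_px)
  thr <- stats::quantile(s, 1 - ori_fraction)
  out <- ifelse(s >= thr, "orientation", "color")
  dim(out) <- c(n_rows, n_cols)
  out
}

# Compact domain profile: super-Gaussian exp(-ln2 * (r/r0)^8) equals 0.5 at
# r = r0; the planted mask is profile >= 0.5, giving a sharp-edged blob of
# equivalent diameter 2*r0 with a narrow soft rim.
domain_profile_blob <- function(n_rows, n_cols, center, r0_px) {
  dr <- seq_len(n_rows) - center[1]
  dc <- seq_len(n_cols) - center[2]
  r2 <- outer(dr^2, dc^2, "+")
  exp(-log(2) * (r2 / r0_px^2)^4)
}

curve_orientation_deg <- function(orient) {
  c(up = 0, left = 90, down = 180, right = 270)[[orient]]
}

# Place curvature domains (independent blobs and/or planted progressions)
# inside orientation bands, with rejection sampling for non-overlap.
plant_domains <- function(n_rows, n_cols, pixel_size_mm, band,
                          n_domains, diam_range, ratios, orients,
                          progressions, min_separation_mm = 0.1) {
  margin_px <- min_separation_mm / pixel_size_mm
  profile <- matrix(0, n_rows, n_cols)
  ratio_pref <- matrix(0, n_rows, n_cols)
  orient_pref <- matrix(NA_real_, n_rows, n_cols)
  mask <- matrix(FALSE, n_rows, n_cols)
  rows <- integer(0); cols <- integer(0); rads <- numeric(0)
  dr <- numeric(0); dor <- character(0)
  prog_records <- list()

  ori_band <- band == "orientation"
  add_domain <- function(center, r0_px, ratio, orient) {
    prof <- domain_profile_blob(n_rows, n_cols, center, r0_px)
    prof[!ori_band] <- 0 # domains live inside orientation bands
    new_px <- prof >= 0.5 & !mask
    profile <<- pmax(profile, prof)
    mask <<- mask | (prof >= 0.5)
    ratio_pref[new_px] <<- ratio
    orient_pref[new_px] <<- curve_orientation_deg(orient)
    rows <<- c(rows, center[1]); cols <<- c(cols, center[2])
    rads <<- c(rads, r0_px); dr <<- c(dr, ratio); dor <<- c(dor, orient)
  }
  free_spot <- function(center, r0_px) {
    if (center[1] < r0_px + margin_px || center[1] > n_rows - r0_px - margin_px ||
        center[2] < r0_px + margin_px || center[2] > n_cols - r0_px - margin_px)
      return(FALSE)
    rim_r <- round(pmin(pmax(center[1] + r0_px * sin(seq(0, 2 * pi,
                                                         length.out = 9)),
                             1), n_rows))
    rim_c <- round(pmin(pmax(center[2] + r0_px * cos(seq(0, 2 * pi,
                                                         length.out = 9)),
                             1), n_cols))
    if (!all(band[cbind(c(round(center[1]), rim_r),
                        c(round(center[2]), rim_c))] == "orientation"))
      return(FALSE)
    if (length(rows) == 0) return(TRUE)
    d <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
    all(d > rads + r0_px + margin_px)
  }

  if (!is.null(progressions)) {
    pr_ratios <- progressions$ratios
    spacing_px <- progressions$spacing_mm / pixel_size_mm
    pr_diam <- if (!is.null(progressions$diameter_mm))
      progressions$diameter_mm else 0.35
    r0 <- pr_diam / 2 / pixel_size_mm
    for (p in seq_len(progressions$n)) {
      ok <- FALSE
      for (try in seq_len(20000)) {
        anchor <- c(stats::runif(1, 1, n_rows), stats::runif(1, 1, n_cols))
        theta <- stats::runif(1, 0, 2 * pi)
        centers <- lapply(seq_along(pr_ratios), function(k)
          anchor + k * spacing_px * c(sin(theta), cos(theta)))
        if (free_spot(anchor, r0) &&
            all(vapply(centers, free_spot, TRUE, r0_px = r0))) {
          ok <- TRUE
          break
        }
      }
      if (!ok)
        stop("could not place planted progression ", p,
             ": domains too large or grid too crowded", call. = FALSE)
      orient <- orients[1 + (p - 1) %% length(orients)]
      for (k in seq_along(pr_ratios))
        add_domain(centers[[k]], r0, pr_ratios[k], orient)
      prog_records[[p]] <- list(
        straight_centroid_mm = (anchor - 1) * pixel_size_mm,
        ratios = pr_ratios,
        centroids_mm = lapply(centers, function(ct) (ct - 1) * pixel_size_mm),
        orientation = orient)
    }
  }

  if (n_domains > 0) {
    for (d in seq_len(n_domains)) {
      ok <- FALSE
      for (try in seq_len(10000)) {
        r0 <- stats::runif(1, diam_range[1], diam_range[2]) / 2 /
          pixel_size_mm
        center <- c(stats::runif(1, 1, n_rows), stats::runif(1, 1, n_cols))
        if (free_spot(center, r0)) { ok <- TRUE; break }
      }
      if (!ok)
        stop("could not place curvature domain ", d,
             ": domains too large for the orientation bands", call. = FALSE)
      add_domain(center,
                 r0,
                 ratios[sample.int(length(ratios), 1)],
                 orients[sample.int(length(orients), 1)])
    }
  }

  domains <- data.frame(
    row = rows, col = cols, radius_px = rads,
    diameter_mm = 2 * rads * pixel_size_mm,
    ratio = dr, curve_orientation = dor,
    stringsAsFactors = FALSE)
  list(profile = profile, mask = mask, ratio_pref = ratio_pref,
       orient_pref = orient_pref, domains = domains,
       progressions = prog_records)
}

# Curvature-degree axis: straight contours sit at 0, curved contours at
# log(1 + ratio); tuning is Gaussian on this axis.
degree_axis <- function(ratio) log1p(ratio)

#' Peak tuning response of model pixels to a stimulus
#'
#' Multiplicative tuning encoding the response phenomenology of
#' curvature-mapped cortex.  A band gate restricts colour-band pixels to
#' chromatic stimuli and orientation-band pixels to achromatic ones.  For
#' straight stimuli, pixels carry a 180-periodic von Mises orientation term
#' scaled by their orientation selectivity; curvature-domain pixels respond
#' at `straight_gain` (an order of magnitude below their curved optimum).
#' For curved stimuli, curvature-domain pixels respond
#' through the degree term and a 360-periodic von Mises term on curve
#' (apex) orientation, while pixels outside the domains respond at their
#' orientation-averaged level (a drifting curved grating sweeps the local
#' orientations of its flanks), so curved-vs-straight contrasts cancel
#' outside genuine curvature domains.  Scrambled gratings drive an untuned
#' response at `scramble_gain`.  Blanks drive nothing.  The result is the
#' pixel's peak |dR/R| for the condition,
#' `amplitude_map * tuning in [0, amplitude_map]`.
#'
#' @param model A [make_cortical_model()] object.
#' @param spec A [stimulus_spec()].
#' @param pixel Optional `c(row, col)`; when `NULL` the full grid is
#'   returned.
#' @return A matrix (or scalar for a single pixel) of peak response
#'   fractions.
#' @export
tuning_response <- function(model, spec, pixel = NULL) {
  stopifnot(inherits(model, "cortical_model"),
            inherits(spec, "stimulus_spec"))
  amp <- model$amplitude_map
  if (spec$kind == "blank") {
    out <- amp * 0
  } else {
    gate <- if (isTRUE(spec$chromatic)) {
      (model$band_map == "color") * 1
    } else {
      (model$band_map == "orientation") * 1
    }
    if (isTRUE(spec$chromatic)) {
      tuning <- gate # colour response carries no orientation/curvature tuning
    } else if (spec$kind == "scrambled_grating") {
      tuning <- gate * model$scramble_gain
    } else {
      ratio_s <- spec$curvature_ratio
      curved <- spec$kind %in% c("curved_grating", "curved_line")
      # straight-contour orientation of the stimulus: the central axis for
      # curved stimuli (up/down apices have horizontal central contours)
      stim_theta <- if (curved) {
        if (spec$curve_orientation %in% c("up", "down")) 0 else 90
      } else spec$orientation_deg
      dtheta <- (model$orientation_angle_map - stim_theta) * pi / 90
      vm180 <- exp(model$orientation_kappa * (cos(dtheta) - 1))
      m <- model$orientation_magnitude_map
      ori_term <- (1 - m) + m * vm180
      u_s <- degree_axis(ratio_s)
      u_p <- degree_axis(model$curvature_ratio_pref_map)
      deg_term <- exp(-(u_s - u_p)^2 / (2 * model$degree_sigma^2))
      if (!curved) {
        # straight stimuli: orientation tuning everywhere; curvature-domain
        # pixels respond to straight contours weakly (straight_gain, an
        # order of magnitude below their curved optimum) and without
        # orientation preference
        tuning <- gate * ori_term
        in_dom <- model$curvature_domain_mask
        tuning[in_dom] <- (gate * model$straight_gain)[in_dom]
      } else {
        # curved stimuli: outside curvature domains a drifting curved
        # grating sweeps through the local orientations of its flanks and
        # drives orientation columns at their orientation-averaged level,
        # so the curved-minus-straight contrast cancels there; inside
        # domains the response is carried by the degree and apex
        # (curve-orientation) terms
        kor <- model$orientation_kappa
        vbar <- exp(-kor) * besselI(kor, 0)
        m <- model$orientation_magnitude_map
        tuning <- gate * ((1 - m) + m * vbar)
        in_dom <- model$curvature_domain_mask
        dphi <- (model$curvature_orient_pref_map -
                   curve_orientation_deg(spec$curve_orientation)) * pi / 180
        co <- exp(model$curve_orientation_kappa_map * (cos(dphi) - 1))
        tuning[in_dom] <- (gate * deg_term * co)[in_dom]
      }
    }
    out <- amp * tuning
  }
  if (is.null(pixel)) out else out[pixel[1], pixel[2]]
}

# Centre distance of two equal disks of radius r whose intersection-over-
# union equals the target (solved from the circular-lens area).
disk_pair_distance <- function(r, iou_target) {
  lens_area <- function(d) {
    if (d <= 0) return(pi * r^2)
    if (d >= 2 * r) return(0)
    2 * r^2 * acos(d / (2 * r)) - d / 2 * sqrt(4 * r^2 - d^2)
  }
  target_lens <- 2 * pi * r^2 * iou_target / (1 + iou_target)
  stats::uniroot(function(d) lens_area(d) - target_lens,
                 c(1e-9, 2 * r - 1e-9))$root
}

#' Synthetic cortex with opposing curve-orientation subdomain pairs
#'
#' Builds a [make_cortical_model()]-style ground truth in which each
#' curvature domain is a pair of equal disks -- one preferring an apex
#' orientation, the other the opposite -- whose planted masks overlap at a
#' controlled intersection-over-union.  Pixels in the overlap respond to
#' both apex orientations (their curve-orientation tuning is flat);
#' exclusive pixels are sharply tuned, so opposing-orientation maps occupy
#' roughly complementary territory, as orientation-pair analyses of
#' curvature domains report.
#'
#' @param n_pairs Number of planted disk pairs.
#' @param pair_overlap Planted intersection-over-union of the two disks of
#'   a pair (the field reports ~20 percent overlap of opposing-orientation
#'   pixel sets within curvature domains).
#' @param domain_diameter_mm Disk diameter, mm.
#' @param orientations `c(first, second)` opposing apex orientations.
#' @param ratio Preferred curvature ratio of all pair pixels.
#' @param pair_kappa Curve-orientation von Mises concentration of the
#'   exclusive (non-overlap) pixels; the overlap pixels get 0.
#' @param amplitude Flat peak |dR/R| amplitude of pair pixels.
#' @inheritParams make_cortical_model
#' @return A `cortical_model` with an extra `pair_masks` element: logical
#'   matrices `first` and `second` (the planted masks) and the achieved
#'   planted overlap percentage `planted_overlap_pct`.
#' @export
make_orientation_pair_model <- function(n_rows = 256, n_cols = 256,
                                        pixel_size_mm = 0.01,
                                        n_pairs = 4,
                                        pair_overlap = 0.2,
                                        domain_diameter_mm = 0.4,
                                        orientations = c("up", "down"),
                                        ratio = 5,
                                        pair_kappa = 4,
                                        amplitude = 2e-4,
                                        map_wavelength_mm = 0.7,
                                        min_separation_mm = 0.1,
                                        seed = 1L) {
  model <- make_cortical_model(
    n_rows = n_rows, n_cols = n_cols, pixel_size_mm = pixel_size_mm,
    map_wavelength_mm = map_wavelength_mm,
    orientation_band_fraction = 1, n_domains = 0,
    amplitude_range = c(amplitude, amplitude),
    curve_orientation_kappa = pair_kappa,
    min_separation_mm = min_separation_mm, seed = seed)
  r_px <- domain_diameter_mm / 2 / pixel_size_mm
  d_px <- disk_pair_distance(r_px, pair_overlap)
  footprint <- r_px + d_px / 2 # half-extent of one pair along its axis
  margin <- footprint + min_separation_mm / pixel_size_mm
  sep <- 2 * footprint + min_separation_mm / pixel_size_mm
  first <- matrix(FALSE, n_rows, n_cols)
  second <- matrix(FALSE, n_rows, n_cols)
  with_seed(child_seed(seed, 77), {
    layout <- NULL
    for (restart in seq_len(200)) {
      centers <- matrix(numeric(0), ncol = 2)
      thetas <- numeric(0)
      for (p in seq_len(n_pairs)) {
        ok <- FALSE
        for (try in seq_len(2000)) {
          ctr <- c(stats::runif(1, margin, n_rows - margin),
                   stats::runif(1, margin, n_cols - margin))
          if (nrow(centers) == 0 ||
              all(sqrt((centers[, 1] - ctr[1])^2 +
                         (centers[, 2] - ctr[2])^2) > sep)) {
            ok <- TRUE
            break
          }
        }
        if (!ok) break
        centers <- rbind(centers, ctr)
        thetas <- c(thetas, stats::runif(1, 0, 2 * pi))
      }
      if (nrow(centers) == n_pairs) {
        layout <- list(centers = centers, thetas = thetas)
        break
      }
    }
    if (is.null(layout))
      stop("could not place ", n_pairs, " orientation pairs", call. = FALSE)
    for (p in seq_len(n_pairs)) {
      ctr <- layout$centers[p, ]
      off <- d_px / 2 * c(sin(layout$thetas[p]), cos(layout$thetas[p]))
      first <- first | disk_mask(n_rows, n_cols, ctr + off, r_px)
      second <- second | disk_mask(n_rows, n_cols, ctr - off, r_px)
    }
  })
  both <- first & second
  model$curvature_domain_mask <- first | second
  model$curvature_ratio_pref_map[] <- 0
  model$curvature_ratio_pref_map[first | second] <- ratio
  model$curvature_orient_pref_map[] <- NA_real_
  model$curvature_orient_pref_map[first] <- curve_orientation_deg(orientations[1])
  model$curvature_orient_pref_map[second & !first] <-
    curve_orientation_deg(orientations[2])
  model$curve_orientation_kappa_map[] <- pair_kappa
  model$curve_orientation_kappa_map[both] <- 0
  model$domain_profile <- (first | second) * 1
  model$pair_masks <- list(
    first = first, second = second,
    orientations = orientations,
    planted_overlap_pct = 100 * sum(both) / sum(first | second))
  model
}

disk_mask <- function(n_rows, n_cols, center, r_px) {
  dr <- seq_len(n_rows) - center[1]
  dc <- seq_len(n_cols) - center[2]
  outer(dr^2, dc^2, "+") <= r_px^2
}
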