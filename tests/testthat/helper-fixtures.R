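# Shared fixtures: small stimulus batteries and sessions built in code.

# The standard achromatic battery: curved gratings at the given ratios and
# apex orientations plus the four straight orientations (and optionally a
# blank).
battery <- function(ratios = 5, orients = c("up", "down", "left", "right"),
                    blank = FALSE) {
  b <- list()
  for (o in orients) for (r in ratios)
    b[[paste0("curved_", o, "_r", r)]] <-
      stimulus_spec("curved_grating", curvature_ratio = r,
                    curve_orientation = o)
  for (a in c(0, 45, 90, 135))
    b[[paste0("straight_", a)]] <-
      stimulus_spec("straight_grating", orientation_deg = a)
  if (blank) b$blank <- stimulus_spec("blank")
  b
}

curved_ids <- function(b) grep("^curved", names(b), value = TRUE)
straight_ids <- function(b) grep("^straight", names(b), value = TRUE)

# A small quiet session for I/O and timecourse mechanics (not for SNR).
tiny_session <- function(seed = 1, n_trials = 4, n = 64, conds = NULL) {
  m <- make_cortical_model(n_rows = n, n_cols = n, n_domains = 2,
                           domain_diameter_mm = c(0.15, 0.2),
                           orientation_band_fraction = 0.85,
                           min_separation_mm = 0.03, seed = seed)
  if (is.null(conds))
    conds <- list(curved = stimulus_spec("curved_grating",
                                         curvature_ratio = 5),
                  straight = stimulus_spec("straight_grating"),
                  blank = stimulus_spec("blank"))
  simulate_session(m, conds, n_trials = n_trials, seed = seed + 1)
}

# Independent winding-number oracle for pinwheel counting: explicit loop
# over plaquettes (column-major, matching which()'s ordering), kept free of
# the package's vectorised implementation.
oracle_pinwheels <- function(angle) {
  wrap <- function(x) x - 180 * round(x / 180)
  out <- NULL
  for (j in seq_len(ncol(angle) - 1)) {
    for (i in seq_len(nrow(angle) - 1)) {
      s <- wrap(angle[i, j + 1] - angle[i, j]) +
        wrap(angle[i + 1, j + 1] - angle[i, j + 1]) +
        wrap(angle[i + 1, j] - angle[i + 1, j + 1]) +
        wrap(angle[i, j] - angle[i + 1, j])
      if (abs(abs(s) - 180) < 1e-6)
        out <- rbind(out, c(i + 0.5, j + 0.5, sign(s)))
    }
  }
  if (is.null(out)) data.frame(row = numeric(0), col = numeric(0),
                               chirality = numeric(0))
  else data.frame(row = out[, 1], col = out[, 2], chirality = out[, 3])
}
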