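# Synthetic cortical architecture: determinism, planted structure, and the
# tuning model's response phenomenology.

test_that("model generation is deterministic and respects planted ranges", {
  m1 <- make_cortical_model(n_rows = 96, n_cols = 96, n_domains = 3,
                            domain_diameter_mm = c(0.2, 0.3),
                            orientation_band_fraction = 0.85,
                            min_separation_mm = 0.05, seed = 4)
  m2 <- make_cortical_model(n_rows = 96, n_cols = 96, n_domains = 3,
                            domain_diameter_mm = c(0.2, 0.3),
                            orientation_band_fraction = 0.85,
                            min_separation_mm = 0.05, seed = 4)
  expect_identical(m1, m2)
  expect_true(all(m1$amplitude_map >= 1e-4 & m1$amplitude_map <= 3e-4))
  expect_true(all(m1$domains$diameter_mm >= 0.2 - 1e-9 &
                    m1$domains$diameter_mm <= 0.3 + 1e-9))
  expect_true(all(m1$orientation_angle_map >= 0 &
                    m1$orientation_angle_map < 180))
  # curvature domains are planted inside orientation bands
  ctr <- round(as.matrix(m1$domains[, c("row", "col")]))
  expect_true(all(m1$band_map[ctr] == "orientation"))
})

test_that("planted progressions have the requested centroid spacing", {
  m <- make_cortical_model(n_rows = 192, n_cols = 192, n_domains = 0,
                           orientation_band_fraction = 1,
                           progressions = list(n = 2, spacing_mm = 0.2,
                                               ratios = c(1, 2, 4),
                                               diameter_mm = 0.3),
                           seed = 11)
  expect_length(m$planted_progressions, 2)
  for (pr in m$planted_progressions) {
    cents <- do.call(rbind, pr$centroids_mm)
    d <- sqrt(rowSums((cents -
      matrix(pr$straight_centroid_mm, nrow(cents), 2, byrow = TRUE))^2))
    expect_equal(d, c(0.2, 0.4, 0.6), tolerance = 1e-9)
  }
})

test_that("recorded pinwheels match a brute-force winding oracle", {
  m <- make_cortical_model(n_rows = 72, n_cols = 72, n_domains = 0,
                           seed = 13)
  oracle <- oracle_pinwheels(m$orientation_angle_map)
  expect_equal(nrow(m$pinwheel_centers), nrow(oracle))
  expect_equal(m$pinwheel_centers$row, oracle$row)
  expect_equal(m$pinwheel_centers$col, oracle$col)
  expect_equal(m$pinwheel_centers$chirality, oracle$chirality)
})

test_that("tuning peaks at the planted preference and gates by band", {
  m <- make_cortical_model(n_rows = 96, n_cols = 96, n_domains = 4,
                           domain_diameter_mm = c(0.15, 0.25),
                           min_separation_mm = 0.05,
                           ratios = 5, curve_orientations = "up", seed = 6)
  spec <- stimulus_spec("curved_grating", curvature_ratio = 5,
                        curve_orientation = "up")
  A <- tuning_response(m, spec)
  sel <- m$curvature_domain_mask
  expect_true(any(sel))
  expect_equal(max(abs(A[sel] / m$amplitude_map[sel] - 1)), 0)
  expect_true(all(A >= 0 & A <= m$amplitude_map))
  # blanks drive nothing; colour-band pixels ignore achromatic stimuli and
  # respond (untuned) to chromatic ones
  expect_true(all(tuning_response(m, stimulus_spec("blank")) == 0))
  expect_true(all(A[m$band_map == "color"] == 0))
  chrom <- tuning_response(m, stimulus_spec("straight_grating",
                                            chromatic = TRUE))
  expect_true(all(chrom[m$band_map == "orientation"] == 0))
  expect_true(any(chrom[m$band_map == "color"] > 0))
  # single-pixel accessor agrees with the full map
  px <- which(sel, arr.ind = TRUE)[1, ]
  expect_identical(tuning_response(m, spec, pixel = px), A[px[1], px[2]])
})

test_that("degree tuning is monotone towards the preferred ratio", {
  m <- make_cortical_model(n_rows = 96, n_cols = 96, n_domains = 3,
                           domain_diameter_mm = c(0.15, 0.25),
                           min_separation_mm = 0.05,
                           ratios = 10, curve_orientations = "up", seed = 8)
  px <- which(m$curvature_ratio_pref_map == 10, arr.ind = TRUE)[1, ]
  resp <- vapply(c(1, 2, 4, 5, 7, 10), function(r)
    tuning_response(m, stimulus_spec("curved_grating", curvature_ratio = r,
                                     curve_orientation = "up"),
                    pixel = px), 1)
  expect_true(all(diff(resp) > 0))
  # straight response of a curvature-domain pixel is an order of magnitude
  # below its curved optimum
  st <- tuning_response(m, stimulus_spec("straight_grating"), pixel = px)
  expect_lt(st, 0.15 * resp[6])
})

test_that("infeasible domain placement raises a placement error", {
  expect_error(
    make_cortical_model(n_rows = 64, n_cols = 64, n_domains = 30,
                        domain_diameter_mm = c(0.45, 0.5), seed = 2),
    "could not place")
})

test_that("orientation-pair models plant the requested mask overlap", {
  pm <- make_orientation_pair_model(n_rows = 192, n_cols = 192, n_pairs = 2,
                                    pair_overlap = 0.2, seed = 3)
  ov <- overlap_percentage(pm$pair_masks$first, pm$pair_masks$second)
  expect_equal(ov, pm$pair_masks$planted_overlap_pct)
  expect_equal(ov, 20, tolerance = 0.1 * 20) # discretised disks
  # overlap pixels respond to both apex orientations, exclusive pixels only
  # to their own
  up <- tuning_response(pm, stimulus_spec("curved_grating",
                                          curvature_ratio = 5,
                                          curve_orientation = "up"))
  dn <- tuning_response(pm, stimulus_spec("curved_grating",
                                          curvature_ratio = 5,
                                          curve_orientation = "down"))
  both <- pm$pair_masks$first & pm$pair_masks$second
  only_up <- pm$pair_masks$first & !pm$pair_masks$second
  expect_equal(up[both], dn[both])
  expect_true(all(up[only_up] > 10 * dn[only_up]))
})
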