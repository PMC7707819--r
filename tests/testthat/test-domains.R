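# Domain detection, connected components, morphometrics, size filtering
# and overlap quantification.

test_that("connectivity flag matters exactly on diagonal touches", {
  mask <- matrix(FALSE, 6, 6)
  mask[1, 1] <- mask[2, 2] <- TRUE # diagonal touch
  mask[5, 5] <- mask[5, 6] <- TRUE # edge touch
  l8 <- curvmap:::label_components(mask, 8)
  l4 <- curvmap:::label_components(mask, 4)
  expect_equal(max(l8), 2)
  expect_equal(max(l4), 3)
  # the 4-connected path agrees with EBImage's labelling
  set.seed(5)
  rnd <- matrix(runif(40 * 40) > 0.7, 40, 40)
  expect_equal(max(curvmap:::label_components(rnd, 4)),
               max(EBImage::bwlabel(rnd * 1)))
  # per-domain pixel counts add up to the labelled area
  ds <- domain_set(curvmap:::label_components(rnd, 8), 0.01)
  expect_equal(sum(ds$domains$n_pixels), sum(rnd))
})

test_that("detect_domains thresholds by p, sign and optional BH adjustment", {
  p1 <- matrix(1, 10, 10)
  t1 <- matrix(-3, 10, 10)
  expect_equal(nrow(detect_domains(t1, p1)$domains), 0)
  # one planted disk of significant pixels -> exactly one label on it
  tmap <- matrix(0.5, 32, 32)
  pmap <- matrix(0.9, 32, 32)
  disk <- outer((1:32 - 16)^2, (1:32 - 16)^2, "+") <= 36
  tmap[disk] <- -5
  pmap[disk] <- 1e-4
  ds <- detect_domains(tmap, pmap, "negative", 0.01, pixel_size_mm = 0.01)
  expect_equal(max(ds$label_image), 1)
  expect_identical(ds$label_image > 0, disk)
  # the positive sign selects nothing here
  expect_equal(nrow(detect_domains(tmap, pmap, "positive")$domains), 0)
  # BH adjustment is at least as strict
  bh <- detect_domains(tmap, pmap, "negative", 0.01, adjust = "BH",
                       pixel_size_mm = 0.01)
  expect_lte(sum(bh$label_image > 0), sum(ds$label_image > 0))
})

test_that("morphometrics match brute-force second moments", {
  px <- 0.01
  disk <- outer((1:80 - 40)^2, (1:80 - 40)^2, "+") <= 20^2
  mm <- domain_morphometry(disk, px)
  expect_equal(mm$equivalent_diameter_mm, 0.4, tolerance = 0.02)
  expect_equal(mm$area_mm2, pi * 0.2^2, tolerance = 0.05 * pi * 0.2^2)
  expect_equal(mm$centroid_mm, c(39, 39) * px, tolerance = 1e-9)
  # 2:1 rectangle against a direct moment computation
  rect <- matrix(FALSE, 60, 60)
  rect[11:50, 21:40] <- TRUE # 40 x 20 px
  mm <- domain_morphometry(rect, px)
  idx <- (which(rect, arr.ind = TRUE) - 1) * px
  cc <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)
  semi <- 2 * sqrt(sort(eigen(cc)$values, decreasing = TRUE))
  expect_equal(mm$semi_axes_mm, semi, tolerance = 1e-12)
  expect_equal(mm$equivalent_diameter_mm, sum(semi), tolerance = 1e-12)
  expect_equal(mm$semi_axes_mm[1] / mm$semi_axes_mm[2], 2, tolerance = 0.05)
  # translation equivariance
  shifted <- matrix(FALSE, 60, 60)
  shifted[11:50 + 7, 21:40 + 3] <- TRUE
  mm2 <- domain_morphometry(shifted, px)
  expect_equal(mm2$centroid_mm, mm$centroid_mm + c(7, 3) * px,
               tolerance = 1e-12)
  expect_equal(mm2$equivalent_diameter_mm, mm$equivalent_diameter_mm,
               tolerance = 1e-12)
  expect_error(domain_morphometry(matrix(FALSE, 3, 3), px), "empty")
})

test_that("small patches are excluded by equivalent diameter", {
  px <- 0.008
  lbl <- matrix(0L, 64, 64)
  lbl[10:34, 10:34] <- 1L # 25 px square: eq diam ~ 0.23 mm at 8 um/px
  lbl[50, 50] <- 2L       # single pixel
  lbl[40:42, 5:7] <- 3L   # 3x3: ~ 0.028 mm
  ds <- domain_set(lbl, px)
  kept <- filter_small_patches(ds, 0.2)
  brute <- sum(ds$domains$eq_diam_mm >= 0.2)
  expect_equal(nrow(kept$domains), brute)
  expect_equal(sort(unique(as.vector(kept$label_image))), c(0L, seq_len(brute)))
  # all-large set is unchanged
  big <- domain_set(matrix(rep(c(0L, 1L), c(500, 524)), 32, 32), 0.05)
  expect_equal(nrow(filter_small_patches(big, 0.2)$domains), 1)
})

test_that("overlap percentage is intersection over union", {
  a <- matrix(FALSE, 20, 20)
  b <- a
  a[1:10, 1:10] <- TRUE
  expect_equal(overlap_percentage(a, a), 100)
  b[15:20, 15:20] <- TRUE
  expect_equal(overlap_percentage(a, b), 0)
  # |A| = |B| = 100, |A n B| = 50 -> 100 * 50 / 150
  a <- matrix(FALSE, 20, 20)
  b <- a
  a[1:5, 1:20] <- TRUE
  b[3:7, 1:20] <- TRUE
  expect_equal(overlap_percentage(a, b), 100 * 60 / 140, tolerance = 1e-12)
  expect_equal(overlap_percentage(a, b, mode = "min"), 60)
  e <- matrix(FALSE, 2, 2)
  expect_warning(z <- overlap_percentage(e, e), "empty")
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "empty"))
  expect_equal(dice_coefficient(a, a), 1)
})

test_that("the ANOVA + Tukey gate agrees with aov/TukeyHSD per pixel", {
  set.seed(11)
  n <- 8
  ga <- list(array(rnorm(4 * 4 * n, mean = -0.5), dim = c(4, 4, n)),
             array(rnorm(4 * 4 * n, mean = -0.4), dim = c(4, 4, n)))
  gb <- list(array(rnorm(4 * 4 * n), dim = c(4, 4, n)),
             array(rnorm(4 * 4 * n), dim = c(4, 4, n)))
  mask <- matrix(TRUE, 4, 4)
  gate <- curvmap:::anova_tukey_gate(ga, gb, mask, 0.05, "negative", "any")
  for (i in 1:4) for (j in 1:4) {
    y <- c(ga[[1]][i, j, ], ga[[2]][i, j, ], gb[[1]][i, j, ], gb[[2]][i, j, ])
    g <- factor(rep(c("a1", "a2", "b1", "b2"), each = n))
    fit <- stats::aov(y ~ g)
    p_f <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    pairs <- c("b1-a1", "b1-a2", "b2-a1", "b2-a2")
    sig <- any(tk[pairs, "p adj"] < 0.05 & tk[pairs, "diff"] > 0)
    expect_equal(gate[i, j], p_f < 0.05 && sig)
  }
})

test_that("domain detection applies the ANOVA gate on top of the t gate", {
  ses <- tiny_session(seed = 13, n_trials = 8)
  cm <- contrast_map(ses, "curved", "straight")
  plain <- detect_domains(cm$t, cm$p, "negative", 0.05,
                          pixel_size_mm = ses$pixel_size_mm)
  groups <- list(a = list(trial_response_maps(ses, "curved")),
                 b = list(trial_response_maps(ses, "straight")))
  gated <- detect_domains(cm$t, cm$p, "negative", 0.05,
                          anova_groups = groups,
                          pixel_size_mm = ses$pixel_size_mm)
  expect_lte(sum(gated$label_image > 0), sum(plain$label_image > 0))
})
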