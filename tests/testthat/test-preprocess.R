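# dR/R normalisation, trial responses, the paired/Welch statistic maps and
# spatial filtering, each against brute-force oracles.

test_that("frame_drr matches its definition and a per-pixel loop oracle", {
  st <- array(100, dim = c(3, 3, 5))
  expect_true(all(frame_drr(st) == 0))
  st[, , 4] <- 99
  expect_equal(frame_drr(st)[, , 4], matrix(-0.01, 3, 3))
  set.seed(1)
  st <- array(exp(rnorm(4 * 3 * 6)), dim = c(4, 3, 6))
  got <- frame_drr(st, n_baseline_frames = 2)
  for (i in 1:4) for (j in 1:3) {
    f0 <- mean(st[i, j, 1:2])
    expect_equal(got[i, j, ], (st[i, j, ] - f0) / f0, tolerance = 1e-12)
  }
  # dR/R is scale-free
  expect_equal(frame_drr(3.7 * st), got, tolerance = 1e-12)
  bad <- st
  bad[2, 3, 1:2] <- 0
  expect_error(frame_drr(bad), "row 2, col 3")
})

test_that("trial_response averages the canonical frame windows", {
  st <- array(100, dim = c(2, 2, 16))
  st[, , 8:16] <- 99
  expect_equal(trial_response(st), matrix(-0.01, 2, 2), tolerance = 1e-12)
  expect_error(trial_response(array(1, dim = c(2, 2, 15))), "16")
  set.seed(2)
  st <- array(exp(rnorm(2 * 2 * 20)), dim = c(2, 2, 20))
  got <- trial_response(st)
  for (i in 1:2) for (j in 1:2) {
    b <- mean(st[i, j, 1:3])
    expect_equal(got[i, j], (mean(st[i, j, 8:16]) - b) / b,
                 tolerance = 1e-12)
  }
})

test_that("paired statistic maps agree with t.test to 1e-10 and are antisymmetric", {
  set.seed(3)
  for (rep in 1:20) {
    a <- array(rnorm(8 * 8 * 5), dim = c(8, 8, 5))
    b <- array(rnorm(8 * 8 * 5), dim = c(8, 8, 5))
    got <- difference_statistic_map(a, b, paired = TRUE)
    swp <- difference_statistic_map(b, a, paired = TRUE)
    expect_identical(swp$t$values, -got$t$values)
    expect_identical(swp$p$values, got$p$values)
    for (i in sample(8, 2)) for (j in sample(8, 2)) {
      tt <- t.test(a[i, j, ], b[i, j, ], paired = TRUE)
      expect_equal(got$t$values[i, j], unname(tt$statistic),
                   tolerance = 1e-10)
      expect_equal(got$p$values[i, j], tt$p.value, tolerance = 1e-10)
    }
  }
})

test_that("degenerate and Welch paths behave as documented", {
  a <- array(rnorm(2 * 2 * 4), dim = c(2, 2, 4))
  same <- difference_statistic_map(a, a, paired = TRUE)
  expect_true(all(same$t$values == 0))
  expect_true(all(same$p$values == 1))
  # constant nonzero difference: infinite t encoded with p = 0
  b <- a + 0.5
  inf <- difference_statistic_map(b, a, paired = TRUE)
  expect_true(all(is.infinite(inf$t$values) & inf$t$values > 0))
  expect_true(all(inf$p$values == 0))
  set.seed(4)
  a <- array(rnorm(3 * 3 * 6), dim = c(3, 3, 6))
  b <- array(rnorm(3 * 3 * 9, sd = 2), dim = c(3, 3, 9))
  w <- difference_statistic_map(a, b, paired = FALSE)
  tt <- t.test(a[2, 2, ], b[2, 2, ])
  expect_equal(w$t$values[2, 2], unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$p$values[2, 2], tt$p.value, tolerance = 1e-10)
  expect_error(difference_statistic_map(a, b, paired = TRUE), "equal trial")
  # the literal xN display scaling is a monotone rescaling of the t map
  n5 <- array(rnorm(2 * 2 * 5), dim = c(2, 2, 5))
  m5 <- array(rnorm(2 * 2 * 5), dim = c(2, 2, 5))
  lit <- difference_statistic_map(n5, m5, scale = "n")
  std <- difference_statistic_map(n5, m5)
  expect_equal(lit$t$values, std$t$values * sqrt(5), tolerance = 1e-12)
  expect_identical(lit$p$values, std$p$values)
})

test_that("map filtering removes DC and low-frequency structure, keeps domains", {
  const <- matrix(5, 64, 64)
  expect_equal(filter_map(const), matrix(0, 64, 64), tolerance = 1e-9)
  # a full-field linear ramp is almost entirely removed
  ramp <- outer(seq(-1, 1, length.out = 128), rep(1, 128))
  f <- filter_map(ramp, 10, 120)
  interior <- f[20:108, 20:108]
  expect_lt(max(abs(interior)), 0.1 * max(abs(ramp)))
  # a 0.4 mm blob (40 px at 10 um/px) survives with >= 80% of its peak
  blob <- matrix(0, 128, 128)
  dr <- outer((1:128 - 64)^2, (1:128 - 64)^2, "+")
  blob[dr <= 20^2] <- 1
  fb <- filter_map(blob, 10, 120)
  expect_gt(fb[64, 64], 0.8)
  expect_error(filter_map(const, 10, 9), "lowfreq_diameter_px")
  # NA pixels are preserved
  withna <- ramp
  withna[3, 5] <- NA
  expect_true(is.na(filter_map(withna)[3, 5]))
})

test_that("contrast maps leave the filtered mean difference intact either way", {
  ses <- tiny_session(seed = 7, n_trials = 6)
  a <- contrast_map(ses, "curved", "straight", filter_trials = TRUE)
  b <- contrast_map(ses, "curved", "straight", filter_trials = FALSE)
  # filtering is linear, so trial-filtered and map-filtered mean
  # differences coincide
  expect_equal(a$diff$values, b$diff$values, tolerance = 1e-10)
  expect_identical(a$t$contrast$A, "curved")
  # identical condition sets give a null map
  same <- contrast_map(ses, "curved", "curved")
  expect_true(all(same$t$values == 0))
})
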