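# Internal helpers shared across the pipeline.

# Evaluate `code` under a local RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards.  All stochastic entry points route through
# this so that package calls never perturb the user's .Random.seed.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a reproducible child seed (kept below .Machine$integer.max).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 10007) %% 2147483647L)
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
}

# Pixel-centre coordinate axis: n pixels covering [-extent/2, extent/2].
centered_axis <- function(n, pitch) {
  (seq_len(n) - (n + 1) / 2) * pitch
}

# Wrap an angle difference (degrees) to [-period/2, period/2).
wrap_angle <- function(x, period = 180) {
  x - period * round(x / period)
}

# Rotate a square matrix 90 degrees counter-clockwise / clockwise.
rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
flip_ud <- function(m) m[nrow(m):1, , drop = FALSE]

# Smoothed standard-normal random field (circular boundary), unit variance
# is not preserved; callers rescale as needed.
smooth_noise_field <- function(n_rows, n_cols, sigma_px) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (sigma_px > 0) z <- gaussian_filter(z, sigma_px)
  z / max(abs(z))
}

# Gaussian filter (replicate boundary) via EBImage::filter2.
gaussian_filter <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  side <- 2L * as.integer(ceiling(3 * sigma_px)) + 1L
  side <- min(side, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (side < 3L) return(m)
  k <- EBImage::makeBrush(side, shape = "Gaussian", sigma = sigma_px)
  as.matrix(EBImage::filter2(m, k, boundary = "replicate"))
}

# Circular (disc) mean filter, replicate boundary.
disc_mean_filter <- function(m, diameter_px) {
  side <- as.integer(diameter_px)
  if (side %% 2L == 0L) side <- side + 1L
  side <- min(side, 2L * (min(dim(m)) %/% 2L) - 1L)
  if (side < 3L) return(matrix(mean(m), nrow(m), ncol(m)))
  k <- EBImage::makeBrush(side, shape = "disc")
  k <- k / sum(k)
  as.matrix(EBImage::filter2(m, k, boundary = "replicate"))
}
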