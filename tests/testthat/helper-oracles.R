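# Independent oracles and fixture builders shared across test files.

# Brute-force per-pixel Sobel gradient magnitude with replicated borders.
# Deliberately written as an explicit loop, independent of the package's
# FFT-based implementation.
sobel_oracle <- function(gray) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), nrow = 3, byrow = TRUE)
  ky <- t(kx)
  h <- nrow(gray); w <- ncol(gray)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      gx <- 0; gy <- 0
      for (di in -1:1) {
        for (dj in -1:1) {
          ii <- min(max(i + di, 1), h)
          jj <- min(max(j + dj, 1), w)
          gx <- gx + kx[di + 2, dj + 2] * gray[ii, jj]
          gy <- gy + ky[di + 2, dj + 2] * gray[ii, jj]
        }
      }
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

# Per-column loop oracle for the mean/std/min/max slide aggregation.
aggregate_oracle <- function(m) {
  d <- ncol(m)
  out <- numeric(4 * d)
  for (j in seq_len(d)) {
    col <- m[, j]
    mu <- sum(col) / length(col)
    out[j] <- mu
    out[d + j] <- sqrt(sum((col - mu)^2) / (length(col) - 1))
    out[2 * d + j] <- min(col)
    out[3 * d + j] <- max(col)
  }
  out
}

# Render an RGB image from independent per-pixel H/E concentration fields
# through a known stain basis (the Beer-Lambert construction used to test
# stain estimation and normalization).
two_stain_image <- function(conc_h, conc_e, stain_matrix) {
  od <- cbind(as.vector(conc_h), as.vector(conc_e)) %*% t(stain_matrix)
  img <- round(pmin(pmax(256 * 10^(-od) - 1, 0), 255))
  array(c(img[, 1], img[, 2], img[, 3]), dim = c(dim(conc_h), 3))
}

# Constant-valued RGB image.
flat_rgb <- function(h, w, value) {
  array(value, dim = c(h, w, 3))
}

angle_deg <- function(a, b) {
  acos(pmin(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# Small single-tissue embedding dataset with planted RIN signal, memoised so
# several test files can share it without regenerating.
shared_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_embedding_dataset(synthetic_spec(
        n_tissues = 1, slides_per_tissue = 200, d = 32, seed = 42
      ))
    }
    cache
  }
})

# Larger single-tissue dataset matching the planted-signal study conditions
# (n = 500, d = 64, 5 signal features, noise 0.5x signal SD).
shared_dataset_500 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_embedding_dataset(synthetic_spec(
        n_tissues = 1, slides_per_tissue = 500, d = 64,
        n_signal_features = 5, noise_sd = 0.5, seed = 1
      ))
    }
    cache
  }
})

# Seeded permutation that leaves the caller's RNG untouched.
with_seed_sample <- function(x, seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample(x)
}
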