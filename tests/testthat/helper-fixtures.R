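# Shared helpers for the suite. Fixtures are generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# a reproducible positive test image (no clipping on normalization)
random_image <- function(side = 64, seed = 1) {
  withr::with_seed(seed, new_lum_image(matrix(runif(side^2, 10, 20), side)))
}

# plant radially symmetric Gaussian bumps on a flat matrix
planted_bumps <- function(side, centers, heights, sigma = 3) {
  v <- matrix(0, side, side)
  for (i in seq_len(nrow(centers))) {
    r2 <- outer((seq_len(side) - centers[i, 2])^2,
                (seq_len(side) - centers[i, 1])^2, "+")
    v <- v + heights[i] * exp(-r2 / (2 * sigma^2))
  }
  v
}

# brute-force strict 8-neighbor local maxima of a matrix (oracle for
# local_extrema), interior pixels only
brute_local_max <- function(v) {
  out <- NULL
  for (i in 2:(nrow(v) - 1)) {
    for (j in 2:(ncol(v) - 1)) {
      nb <- v[(i - 1):(i + 1), (j - 1):(j + 1)]
      if (v[i, j] > max(nb[-5])) out <- rbind(out, c(j, i, v[i, j]))
    }
  }
  if (is.null(out)) return(data.frame(x = numeric(0), y = numeric(0), a = numeric(0)))
  out <- data.frame(x = out[, 1], y = out[, 2], a = out[, 3])
  out[order(-out$a, out$y, out$x), ]
}

# quietly build a normalized modulated-texture fixture (clipping warnings from
# deep modulation are expected and irrelevant to most tests)
quiet_texture <- function(...) suppressWarnings(make_modulated_texture(...))
quiet_face <- function(...) suppressWarnings(make_schematic_face(...))

expect_equal_tol <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
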