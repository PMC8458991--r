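# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the DFT oracle builds explicit transform
# matrices instead of calling fft(), the mask oracle evaluates the gain
# formula in a double loop, and the Spearman oracle goes rank-then-Pearson.

# direct DFT via explicit exponential matrices (no fft())
dftMatrix <- function(n, inverse = FALSE) {
  s <- if (inverse) 2i else -2i
  outer(0:(n - 1), 0:(n - 1), function(j, k) exp(s * pi * j * k / n))
}

# brute-force Butterworth mask over integer offsets from the DC position
bruteMask <- function(n, r, order) {
  m <- matrix(0, n, n)
  dc <- floor(n / 2)
  for (i in 1:n) for (j in 1:n) {
    d <- sqrt((i - 1 - dc)^2 + (j - 1 - dc)^2)
    m[i, j] <- 1 / (1 + (sqrt(2) - 1) * (d / r)^(2 * order))
  }
  m
}

# low-pass filter an image through the direct-DFT route with a brute mask;
# the centered mask is moved to fft order by an explicit modular reindex
bruteLowpass <- function(x, r, order, complement = FALSE) {
  n <- nrow(x)
  m <- bruteMask(n, r, order)
  if (complement) m <- 1 - m
  dc <- floor(n / 2)
  un <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n)
    un[i, j] <- m[(i - 1 + dc) %% n + 1, (j - 1 + dc) %% n + 1]
  Fm <- dftMatrix(n)
  Im <- dftMatrix(n, inverse = TRUE)
  spec <- Fm %*% x %*% Fm
  Re(Im %*% (spec * un) %*% Im) / n^2
}

# Spearman via explicit average ranks then product-moment correlation
spearmanOracle <- function(a, b) {
  ra <- rank(a, ties.method = "average")
  rb <- rank(b, ties.method = "average")
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# all permutations of 1..n (n small), lexicographic
allPermutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in allPermutations(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# deterministic 8x8 ramp fixture in [0, 1]
rampImage <- function(n = 8) {
  outer(seq(0, 1, length.out = n), seq(0, 1, length.out = n),
        function(a, b) (a + b) / 2)
}

# small textured fixture with content across the spectrum
mixedImage <- function(n = 8, seed = 42) {
  set.seed(seed)
  clipped <- matrix(runif(n * n), n)
  (clipped + rampImage(n)) / 2
}
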