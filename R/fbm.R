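# Fractional Brownian motion synthesis by circulant embedding.
#
# Increments of fBm with Hurst exponent H (fractional Gaussian noise) have
# autocovariance gamma(h) = (|h+1|^2H - 2|h|^2H + |h-1|^2H) / 2. Embedding
# the n x n Toeplitz covariance in a 2n x 2n circulant matrix diagonalises
# it by the DFT; for fGn all circulant eigenvalues are non-negative, so the
# synthesis is exact (no truncation), and the sample path is recovered by a
# cumulative sum of the simulated increments.

# Circulant eigenvalues for an fGn block of length n at Hurst exponent H.
fgnEigenvalues <- function(n, hurst) {
  h <- 0:n
  g <- 0.5 * (abs(h + 1)^(2 * hurst) - 2 * abs(h)^(2 * hurst) +
                abs(h - 1)^(2 * hurst))
  ev <- Re(stats::fft(c(g, g[n:2])))  # length 2n
  # numerically tiny negatives can appear at extreme H; clamp at zero
  pmax(ev, 0)
}

# Draw `nPaths` fBm paths of length n as columns, consuming the current RNG
# stream. `ev` are precomputed circulant eigenvalues for (n, H).
fbmPathsFromStream <- function(n, ev, nPaths) {
  m <- 2L * n
  z <- matrix(stats::rnorm(m * nPaths), m, nPaths) +
    1i * matrix(stats::rnorm(m * nPaths), m, nPaths)
  w <- stats::mvfft(sqrt(ev / (2 * m)) * z)
  fgn <- Re(w[seq_len(n), , drop = FALSE])
  apply(fgn, 2L, cumsum)
}

#' Generate a fractional Brownian motion sample path
#'
#' Exact synthesis via circulant embedding of the fractional-Gaussian-noise
#' covariance. fBm gives the synthetic-data module signals of controllable
#' complexity: the theoretical fractal dimension of a path with Hurst
#' exponent `hurst` is `D = 2 - hurst`, so lower `hurst` means a rougher,
#' more complex signal.
#'
#' @param nSamples path length (>= 16).
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param seed integer seed; the same arguments always return a
#'   bit-identical path, and the caller's RNG state is left untouched.
#' @return numeric vector of length `nSamples`.
#' @examples
#' x <- generateFbm(500, 0.7, seed = 1)
#' stopifnot(identical(x, generateFbm(500, 0.7, seed = 1)))
#' @export
generateFbm <- function(nSamples, hurst, seed) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop("hurst must lie strictly inside (0, 1)", call. = FALSE)
  nSamples <- as.integer(nSamples)
  if (nSamples < 16L) stop("nSamples must be >= 16", call. = FALSE)
  ev <- fgnEigenvalues(nSamples, hurst)
  withSeed(seed, drop(fbmPathsFromStream(nSamples, ev, 1L)))
}
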