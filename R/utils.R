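# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# DFT frequencies in cycles/sample for length n (numpy fftfreq layout).
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  ifelse(k > n %/% 2, k - n, k) / n
}

# Gaussian low-pass of a matrix via the frequency domain (circular boundary).
fft_gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  fy <- fft_freqs(nrow(m))
  fx <- fft_freqs(ncol(m))
  h <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, "+"))
  Re(stats::fft(stats::fft(m) * h, inverse = TRUE)) / length(m)
}

# Bilinear interpolation of matrix `m` at fractional (row, col) positions.
interp_bilinear <- function(m, row, col) {
  row <- as.vector(row)
  col <- as.vector(col)
  row <- pmin(pmax(row, 1), nrow(m))
  col <- pmin(pmax(col, 1), ncol(m))
  r0 <- pmin(floor(row), nrow(m) - 1L)
  c0 <- pmin(floor(col), ncol(m) - 1L)
  wr <- row - r0
  wc <- col - c0
  m[cbind(r0, c0)] * (1 - wr) * (1 - wc) +
    m[cbind(r0 + 1, c0)] * wr * (1 - wc) +
    m[cbind(r0, c0 + 1)] * (1 - wr) * wc +
    m[cbind(r0 + 1, c0 + 1)] * wr * wc
}

# Logical mask of pixels within `radius_px` of (row0, col0) on an nr x nc grid.
disc_mask <- function(nr, nc, row0, col0, radius_px) {
  outer((seq_len(nr) - row0)^2, (seq_len(nc) - col0)^2, "+") <= radius_px^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
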