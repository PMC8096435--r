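# Shared fixtures and independent oracles used across test files.

# Smooth speckle texture (band-limited Gaussian noise), offset so intensity
# stays positive.
make_speckle <- function(n = 96, sigma = 1, seed = 99) {
  set.seed(seed)
  tex <- matrix(rnorm(n * n), n, n)
  tex <- blastoquant:::fft_gauss_blur(tex, sigma)
  tex / sd(tex) * 100 + 500
}

# Exact subpixel translation of a periodic image via a Fourier phase ramp.
fourier_shift <- function(m, dy, dx) {
  fy <- blastoquant:::fft_freqs(nrow(m))
  fx <- blastoquant:::fft_freqs(ncol(m))
  ph <- exp(-2i * pi * outer(fy * dy, fx * dx, "+"))
  Re(fft(fft(m) * ph, inverse = TRUE)) / length(m)
}

# Two-frame movie showing a true linear translation (dy rows, dx cols),
# built by cropping shifted views of a larger texture so no window content
# is invented at the edges.
shifted_pair_movie <- function(dy, dx, n = 96, sigma = 1, seed = 99) {
  big <- make_speckle(n + 24, sigma, seed)
  a <- big[13:(12 + n), 13:(12 + n)]
  b <- big[(13 - dy):(12 + n - dy), (13 - dx):(12 + n - dx)]
  movie(array(c(a, b), dim = c(n, n, 2)), pixel_size = 1, frame_interval = 1)
}

# Interior mask keeping vectors one pass-1 window away from the frame edge
# (edge windows legitimately lose content to the frame boundary).
interior_mask <- function(n = 96, margin = 20) {
  m <- matrix(FALSE, n, n)
  m[(margin + 1):(n - margin), (margin + 1):(n - margin)] <- TRUE
  m
}

# Brute-force argmax of the full-frame linear cross-correlation (the
# integer-displacement oracle), searched over a small lag range.
brute_force_shift <- function(a, b, max_lag = 6) {
  a <- a - mean(a); b <- b - mean(b)
  n <- nrow(a)
  best <- c(NA, NA); best_v <- -Inf
  for (dy in -max_lag:max_lag) {
    for (dx in -max_lag:max_lag) {
      ra <- max(1, 1 - dy):min(n, n - dy)
      ca <- max(1, 1 - dx):min(n, n - dx)
      v <- sum(a[ra, ca] * b[ra + dy, ca + dx]) / (length(ra) * length(ca))
      if (v > best_v) { best_v <- v; best <- c(dy, dx) }
    }
  }
  best
}

# Brute-force single-linkage chaining of division times: build the
# within-gap adjacency graph and label connected components in time order.
brute_force_waves <- function(times, gap = 0.5) {
  n <- length(times)
  if (n == 0) return(integer(0))
  adj <- abs(outer(times, times, "-")) <= gap + 1e-9
  comp <- rep(0L, n)
  cur <- 0L
  for (i in order(times)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      frontier <- i
      comp[i] <- cur
      while (length(frontier)) {
        nb <- which(adj[frontier[1], ] & comp == 0L)
        comp[nb] <- cur
        frontier <- c(frontier[-1], nb)
      }
    }
  }
  comp
}

# Closed-form Yates-corrected chi-squared statistic for a 2x2 table.
chi2_yates_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
}

# Exhaustive Mann-Whitney oracle: U by pair counting and two-sided p by
# enumerating every labeling of the pooled sample.
mann_whitney_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  u_pairs <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  U <- u_pairs(x, y)
  mu <- nx * ny / 2
  combos <- combn(nx + ny, nx)
  us <- apply(combos, 2, function(idx) u_pairs(pooled[idx], pooled[-idx]))
  list(U = U, p = mean(abs(us - mu) >= abs(U - mu) - 1e-9))
}
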