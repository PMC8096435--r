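# Two-pass cross-correlation particle image velocimetry.
#
# Pass 1 cross-correlates coarse interrogation windows on a regular grid to
# obtain integer predictor displacements; pass 2 re-correlates finer windows
# whose search regions are offset by the rounded pass-1 prediction, with
# three-point Gaussian subpixel peak localisation. Correlation is computed
# in the frequency domain after window mean subtraction. Outliers are
# flagged by the normalized median test and replaced by the local median.

# Linear (zero-padded) cross-correlation peak of two equally sized windows,
# normalized by the overlap area so large displacements are not penalised,
# with the search restricted to +/- max_disp. Returns list(dy, dx, ccn, ri,
# ci) where ccn is the normalized correlation over lags
# -(max_disp+1)..(max_disp+1) (so subpixel neighbours always exist), or
# NULL when a window has zero variance.
xcorr_peak <- function(a, b, max_disp = NULL) {
  nr <- nrow(a); nc <- ncol(a)
  if (is.null(max_disp)) max_disp <- min(nr, nc) %/% 2
  max_disp <- min(max_disp, nr - 2, nc - 2)
  a <- a - mean(a)
  b <- b - mean(b)
  if (all(a == 0) || all(b == 0)) return(NULL)
  pa <- matrix(0, 2 * nr, 2 * nc); pa[1:nr, 1:nc] <- a
  pb <- matrix(0, 2 * nr, 2 * nc); pb[1:nr, 1:nc] <- b
  cc <- Re(stats::fft(Conj(stats::fft(pa)) * stats::fft(pb), inverse = TRUE))
  lags <- -(max_disp + 1):(max_disp + 1)
  iy <- (lags %% (2 * nr)) + 1
  ix <- (lags %% (2 * nc)) + 1
  ccn <- cc[iy, ix] / outer(nr - abs(lags), nc - abs(lags))
  # peak restricted to the interior (+/- max_disp) so neighbours exist
  interior <- 2:(length(lags) - 1)
  sub <- ccn[interior, interior]
  i <- which.max(sub)
  ri <- ((i - 1) %% length(interior)) + 2
  ci <- ((i - 1) %/% length(interior)) + 2
  list(dy = lags[ri], dx = lags[ci], ccn = ccn, ri = ri, ci = ci)
}

# Three-point subpixel refinement along one axis of the correlation plane.
# Gaussian estimator; parabolic fallback when log of a non-positive value
# would occur.
subpixel_1d <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0 && c0 >= cm && c0 >= cp) {
    den <- 2 * (log(cm) - 2 * log(c0) + log(cp))
    if (den < 0) return((log(cm) - log(cp)) / den)
  }
  den <- 2 * (cm - 2 * c0 + cp)
  if (den < 0) (cm - cp) / den else 0
}

# Subpixel peak of a correlation plane around its integer peak.
xcorr_subpixel <- function(pk) {
  m <- pk$ccn; r <- pk$ri; c <- pk$ci
  dy <- pk$dy + subpixel_1d(m[r - 1, c], m[r, c], m[r + 1, c])
  dx <- pk$dx + subpixel_1d(m[r, c - 1], m[r, c], m[r, c + 1])
  c(dy = dy, dx = dx)
}

#' Velocity field container
#'
#' Per-frame-pair velocity vectors on a regular grid, in physical units.
#' Produced by [piv_two_pass()]; can also be constructed directly (e.g. for
#' synthetic spectral-analysis inputs).
#'
#' @param u,v matrices of x- and y-velocity components in um/s, one row per
#'   vector, one column per frame pair.
#' @param x,y vector positions in um.
#' @param valid logical matrix matching `u`; `FALSE` marks vectors that
#'   failed validation (their values are local-median replacements).
#' @param pixel_size,frame_interval calibration of the source movie.
#' @return An object of class `velocity_field`.
#' @export
velocity_field <- function(u, v, x = NULL, y = NULL, valid = NULL,
                           pixel_size = 1, frame_interval = 1) {
  u <- as.matrix(u); v <- as.matrix(v)
  stopifnot(all(dim(u) == dim(v)))
  if (is.null(valid)) valid <- matrix(TRUE, nrow(u), ncol(u))
  structure(list(u = u, v = v,
                 x = x %||% rep(NA_real_, nrow(u)),
                 y = y %||% rep(NA_real_, nrow(u)),
                 valid = valid,
                 pixel_size = pixel_size, frame_interval = frame_interval),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d vectors x %d frame pairs (%.1f%% valid)\n",
              nrow(x$u), ncol(x$u), 100 * mean(x$valid)))
  invisible(x)
}

#' Two-pass PIV on a movie
#'
#' Runs the two-pass interrogation scheme on every consecutive frame pair.
#' Default windows of 20 and 10 um with 50% overlap reproduce the standard
#' analysis of cortical-contraction movies (yielding on the order of 180
#' in-mask vectors for an 8-cell-stage embryo).
#'
#' @param m a [movie()] with at least 2 frames.
#' @param window_pass1_um,window_pass2_um interrogation window sizes in um;
#'   both must convert to at least 8 px and fit inside the frame.
#' @param overlap window overlap fraction in `[0, 1)` (grid spacing is
#'   `window * (1 - overlap)`).
#' @param mask optional logical H x W matrix (e.g. from [mask_embryo()]);
#'   vectors whose window centre falls outside it are excluded.
#' @param median_threshold normalized median test threshold (vectors above
#'   it are flagged invalid and replaced by the local median); `Inf`
#'   disables validation.
#' @return A [velocity_field()] with velocities in um/s.
#' @export
piv_two_pass <- function(m, window_pass1_um = 20, window_pass2_um = 10,
                         overlap = 0.5, mask = NULL, median_threshold = 2) {
  stopifnot(inherits(m, "movie"))
  d <- dim(m$frames)
  H <- d[1]; W <- d[2]; T <- d[3]
  if (T < 2) stop("movie must have at least 2 frames")
  px <- m$pixel_size
  w1 <- round(window_pass1_um / px)
  w2 <- round(window_pass2_um / px)
  if (w1 < 8 || w2 < 8) stop("interrogation window below 8 px; check pixel size")
  if (w1 > min(H, W)) stop("interrogation window larger than image")
  stopifnot(overlap >= 0, overlap < 1)

  offsets <- function(n, w, s) {
    o <- seq(1L, n - w + 1L, by = max(1L, as.integer(round(s))))
    o
  }
  s1 <- w1 * (1 - overlap)
  s2 <- w2 * (1 - overlap)
  o1r <- offsets(H, w1, s1); o1c <- offsets(W, w1, s1)
  o2r <- offsets(H, w2, s2); o2c <- offsets(W, w2, s2)
  c1r <- o1r + (w1 - 1) / 2; c1c <- o1c + (w1 - 1) / 2
  c2r <- o2r + (w2 - 1) / 2; c2c <- o2c + (w2 - 1) / 2
  g2 <- expand.grid(ri = seq_along(o2r), ci = seq_along(o2c))
  nv <- nrow(g2)

  # vector selection by mask at window centres
  keep <- if (is.null(mask)) rep(TRUE, nv) else {
    stopifnot(is.logical(mask), all(dim(mask) == c(H, W)))
    mask[cbind(round(c2r[g2$ri]), round(c2c[g2$ci]))]
  }
  if (!any(keep)) stop("no embryo: mask excludes every vector")

  # nearest pass-1 grid node for each pass-2 vector
  near1r <- vapply(c2r[g2$ri], function(r) which.min(abs(c1r - r)), 1L)
  near1c <- vapply(c2c[g2$ci], function(c) which.min(abs(c1c - c)), 1L)

  np <- T - 1
  u <- matrix(NA_real_, nv, np)
  v <- matrix(NA_real_, nv, np)
  measured <- matrix(FALSE, nv, np)

  for (p in seq_len(np)) {
    fa <- m$frames[, , p]
    fb <- m$frames[, , p + 1]
    # pass 1: integer predictor on the coarse grid (search limited to w1/4,
    # the usual one-quarter rule), then 3x3 median-smoothed so isolated bad
    # nodes cannot poison the pass-2 window offsets
    d1y <- matrix(0, length(o1r), length(o1c))
    d1x <- matrix(0, length(o1r), length(o1c))
    for (i in seq_along(o1r)) {
      rows <- o1r[i]:(o1r[i] + w1 - 1)
      for (j in seq_along(o1c)) {
        cols <- o1c[j]:(o1c[j] + w1 - 1)
        pk <- xcorr_peak(fa[rows, cols], fb[rows, cols], max_disp = w1 %/% 4)
        if (!is.null(pk)) {
          d1y[i, j] <- pk$dy
          d1x[i, j] <- pk$dx
        }
      }
    }
    d1y <- median_filter3(d1y)
    d1x <- median_filter3(d1x)
    # pass 2: shifted fine windows with subpixel peak
    for (k in seq_len(nv)) {
      if (!keep[k]) next
      orow <- o2r[g2$ri[k]]; ocol <- o2c[g2$ci[k]]
      sy0 <- d1y[near1r[k], near1c[k]]
      sx0 <- d1x[near1r[k], near1c[k]]
      # clamp the predictor so the shifted window stays inside the frame;
      # widen the residual search by whatever the clamp took away
      sy <- min(max(sy0, 1 - orow), H - w2 + 1 - orow)
      sx <- min(max(sx0, 1 - ocol), W - w2 + 1 - ocol)
      extra <- max(abs(sy0 - sy), abs(sx0 - sx))
      a <- fa[orow:(orow + w2 - 1), ocol:(ocol + w2 - 1)]
      b <- fb[(orow + sy):(orow + sy + w2 - 1), (ocol + sx):(ocol + sx + w2 - 1)]
      pk <- xcorr_peak(a, b, max_disp = max(2L, w2 %/% 4) + extra)
      if (is.null(pk)) next  # zero-variance window: leave invalid
      dd <- xcorr_subpixel(pk)
      v[k, p] <- (sy + dd[["dy"]]) * px / m$frame_interval
      u[k, p] <- (sx + dd[["dx"]]) * px / m$frame_interval
      measured[k, p] <- TRUE
    }
  }

  valid <- measured
  if (is.finite(median_threshold)) {
    for (p in seq_len(np)) {
      res <- median_validate(u[, p], v[, p], g2$ri, g2$ci, keep & measured[, p],
                             threshold = median_threshold,
                             eps = 0.1 * px / m$frame_interval)
      u[, p] <- res$u
      v[, p] <- res$v
      valid[, p] <- res$valid & measured[, p]
    }
  }
  # unmeasured in-mask vectors: fall back to frame-pair median
  for (p in seq_len(np)) {
    bad <- keep & !measured[, p]
    if (any(bad)) {
      u[bad, p] <- stats::median(u[keep & measured[, p], p], na.rm = TRUE) %||% 0
      v[bad, p] <- stats::median(v[keep & measured[, p], p], na.rm = TRUE) %||% 0
      u[bad, p][is.na(u[bad, p])] <- 0
      v[bad, p][is.na(v[bad, p])] <- 0
    }
  }

  velocity_field(u[keep, , drop = FALSE], v[keep, , drop = FALSE],
                 x = c2c[g2$ci[keep]] * px, y = c2r[g2$ri[keep]] * px,
                 valid = valid[keep, , drop = FALSE],
                 pixel_size = px, frame_interval = m$frame_interval)
}

# Component-wise 3x3 median filter of an integer displacement field
# (rounded back to integers so window offsets stay aligned to the grid).
median_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      out[i, j] <- stats::median(m[max(1, i - 1):min(nr, i + 1),
                                   max(1, j - 1):min(nc, j + 1)])
    }
  }
  round(out)
}

# Normalized median test (8-neighbourhood on the vector grid) with
# local-median replacement of flagged vectors.
median_validate <- function(u, v, ri, ci, present, threshold = 2, eps = 0.1) {
  n <- length(u)
  nb_med <- function(comp, k, use) {
    sel <- use & abs(ri - ri[k]) <= 1 & abs(ci - ci[k]) <= 1 &
      !(ri == ri[k] & ci == ci[k])
    comp[sel]
  }
  fluct <- rep(0, n)
  for (k in seq_len(n)) {
    if (!present[k]) next
    fu <- 0; fv <- 0
    nu <- nb_med(u, k, present)
    nv <- nb_med(v, k, present)
    if (length(nu) >= 3) {
      mu <- stats::median(nu)
      ru <- stats::median(abs(nu - mu))
      fu <- abs(u[k] - mu) / (ru + eps)
      mv <- stats::median(nv)
      rv <- stats::median(abs(nv - mv))
      fv <- abs(v[k] - mv) / (rv + eps)
    }
    fluct[k] <- sqrt(fu^2 + fv^2)
  }
  ok <- present & fluct <= threshold
  uo <- u; vo <- v
  for (k in which(present & !ok)) {
    nu <- nb_med(u, k, ok)
    nv <- nb_med(v, k, ok)
    uo[k] <- if (length(nu)) stats::median(nu) else 0
    vo[k] <- if (length(nv)) stats::median(nv) else 0
  }
  list(u = uo, v = vo, valid = ok)
}

#' Segment the embryo in a movie
#'
#' Otsu threshold on the temporally averaged frame, keep the largest
#' connected component, and fill holes. The resulting mask restricts PIV
#' vectors to the embryo.
#'
#' @param m a [movie()].
#' @return Logical H x W matrix; all-`FALSE` when no foreground exists
#'   (blank movie).
#' @export
mask_embryo <- function(m) {
  stopifnot(inherits(m, "movie"))
  avg <- apply(m$frames, c(1, 2), mean)
  rng <- range(avg)
  if (diff(rng) < 1e-12) return(matrix(FALSE, nrow(avg), ncol(avg)))
  norm <- (avg - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm > th
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  labm <- EBImage::imageData(lab)
  if (max(labm) == 0) return(matrix(FALSE, nrow(avg), ncol(avg)))
  sizes <- tabulate(labm[labm > 0])
  biggest <- which.max(sizes)
  comp <- EBImage::Image(labm == biggest)
  filled <- EBImage::fillHull(comp)
  matrix(as.logical(EBImage::imageData(filled)), nrow(avg), ncol(avg))
}

#' Export a velocity field as a tidy table
#'
#' @param field a [velocity_field()].
#' @return Data frame with columns `pair`, `x_um`, `y_um`, `u_um_s`,
#'   `v_um_s`, `valid`.
#' @export
as.data.frame.velocity_field <- function(x, ...) {
  np <- ncol(x$u); nv <- nrow(x$u)
  data.frame(pair = rep(seq_len(np), each = nv),
             x_um = rep(x$x, np), y_um = rep(x$y, np),
             u_um_s = as.vector(x$u), v_um_s = as.vector(x$v),
             valid = as.vector(x$valid))
}
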