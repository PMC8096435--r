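# Per-embryo Fourier power spectra of PIV velocities and the band-limited
# oscillation call.

#' Per-embryo velocity power spectrum
#'
#' For every vector and both velocity components, the time series is
#' detrended (mean removed, which also cancels any constant drift), its
#' discrete-Fourier power spectrum computed, and the spectra averaged into
#' one spectrum per embryo. Averaging power (not velocities) preserves
#' out-of-phase pulsations across the cortex. The DC bin is excluded; no
#' taper is applied.
#'
#' @param field a [velocity_field()] with at least 32 frame pairs.
#' @param embryo_id label carried into downstream tables.
#' @param min_valid_frac vectors valid in less than this fraction of frame
#'   pairs are dropped before averaging.
#' @return A data frame of class `power_spectrum` with columns `period_s`
#'   (descending) and `power`, and attributes `embryo_id`, `frame_interval`
#'   and `n_series`.
#' @export
embryo_spectrum <- function(field, embryo_id = "embryo", min_valid_frac = 0.5) {
  stopifnot(inherits(field, "velocity_field"))
  T <- ncol(field$u)
  if (T < 32) stop("need at least 32 time points to resolve the 50-120 s band")
  ok <- rowMeans(field$valid) >= min_valid_frac
  if (!any(ok)) stop("no valid vectors")
  series <- rbind(field$u[ok, , drop = FALSE], field$v[ok, , drop = FALSE])
  series <- sweep(series, 1, rowMeans(series))  # detrend each series
  spec <- Mod(stats::mvfft(t(series)))^2 / T
  bins <- 2:(T %/% 2 + 1)  # one-sided, DC excluded
  power <- rowMeans(spec[bins, , drop = FALSE])
  out <- data.frame(period_s = T * field$frame_interval / (bins - 1),
                    power = power)
  attr(out, "embryo_id") <- embryo_id
  attr(out, "frame_interval") <- field$frame_interval
  attr(out, "n_series") <- nrow(series)
  class(out) <- c("power_spectrum", "data.frame")
  out
}

#' Oscillation call from a power spectrum
#'
#' The amplitude is the peak power within the period band (50-120 s by
#' default, the band where periodic cortical contractions occur); the
#' background is the mean power of the whole DC-excluded spectrum. The
#' embryo is called oscillating when amplitude / background >= threshold
#' (the comparison is inclusive at exactly the threshold).
#'
#' @param spec a [embryo_spectrum()] result (or any data frame with
#'   `period_s` and `power`).
#' @param band period band in seconds, `c(low, high)`.
#' @param threshold amplitude-over-background ratio required to call an
#'   oscillation.
#' @return A list of class `oscillation_call`: `amplitude`, `peak_period`,
#'   `background`, `ratio`, `is_oscillating`, `embryo_id`.
#' @export
call_oscillation <- function(spec, band = c(50, 120), threshold = 1.7) {
  stopifnot(is.data.frame(spec), all(c("period_s", "power") %in% names(spec)),
            length(band) == 2, band[1] < band[2], threshold > 0)
  in_band <- spec$period_s >= band[1] & spec$period_s <= band[2]
  if (!any(in_band)) stop("no spectral bins fall in the requested band")
  background <- mean(spec$power)
  amp_i <- which(in_band)[which.max(spec$power[in_band])]
  amplitude <- spec$power[amp_i]
  ratio <- if (background > 0) amplitude / background else 0
  structure(list(embryo_id = attr(spec, "embryo_id") %||% "embryo",
                 amplitude = amplitude,
                 peak_period = spec$period_s[amp_i],
                 background = background,
                 ratio = ratio,
                 is_oscillating = ratio >= threshold),
            class = "oscillation_call")
}

#' @export
print.oscillation_call <- function(x, ...) {
  cat(sprintf("<oscillation_call> %s: ratio %.2f (peak %.0f s) -> %s\n",
              x$embryo_id, x$ratio, x$peak_period,
              if (x$is_oscillating) "oscillating" else "not oscillating"))
  invisible(x)
}

#' Genotype-averaged power spectrum
#'
#' Pointwise mean and SEM across embryos of the same genotype. All spectra
#' must share one period grid.
#'
#' @param specs list of [embryo_spectrum()] results.
#' @return Data frame `period_s`, `mean_power`, `sem_power`, `n`. With a
#'   single spectrum the SEM is undefined and returned as `NA`.
#' @export
genotype_spectrum <- function(specs) {
  stopifnot(is.list(specs), length(specs) >= 1)
  grid <- specs[[1]]$period_s
  for (s in specs) {
    if (length(s$period_s) != length(grid) ||
        max(abs(s$period_s - grid)) > 1e-9) {
      stop("spectra are not on identical period grids")
    }
  }
  pw <- vapply(specs, function(s) s$power, numeric(length(grid)))
  pw <- matrix(pw, nrow = length(grid))
  n <- ncol(pw)
  data.frame(period_s = grid,
             mean_power = rowMeans(pw),
             sem_power = if (n > 1) apply(pw, 1, stats::sd) / sqrt(n) else NA_real_,
             n = n)
}
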