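# The statistical toolbox used throughout: Welch's t, Mann-Whitney U,
# Yates-corrected chi-squared, Pearson correlation, and group summaries.
# Significance is conventionally reported at p < 1e-2 in summary tables;
# the tests themselves return raw p values.

#' Unpaired two-tailed Welch's t test
#'
#' @param x,y numeric samples (n >= 2 each, finite variance).
#' @return List with `statistic`, `df` (Satterthwaite), `p_value`,
#'   `mean_diff`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2,
            all(is.finite(x)), all(is.finite(y)))
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = mean(x) - mean(y))
}

#' Mann-Whitney U test
#'
#' U is computed from midrank rank sums for the first sample (so x entirely
#' below y gives U = 0). For min(n) <= 8 the two-sided p value is exact,
#' by full enumeration of all choose(nx+ny, nx) group labelings of the
#' pooled sample (which handles ties); otherwise a normal approximation
#' with tie-corrected variance is used.
#'
#' @param x,y numeric samples (n >= 1 each).
#' @param exact force (`TRUE`) or forbid (`FALSE`) enumeration; default
#'   switches at min(n) = 8.
#' @return List with `U`, `p_value` and `method`.
#' @export
mann_whitney <- function(x, y, exact = NULL) {
  stopifnot(length(x) >= 1, length(y) >= 1,
            all(is.finite(x)), all(is.finite(y)))
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  U <- u_of(seq_len(nx))
  if (is.null(exact)) exact <- min(nx, ny) <= 8
  mu <- nx * ny / 2
  if (exact) {
    combos <- utils::combn(nx + ny, nx)
    us <- apply(combos, 2, u_of)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    n <- nx + ny
    ties <- table(pooled)
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (U - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(U = U, p_value = min(p, 1), method = method)
}

#' Pearson's chi-squared test with Yates's continuity correction
#'
#' For a 2 x 2 contingency table: `sum((|O - E| - 0.5)^2 / E)`, with the
#' correction floored so `|O - E| - 0.5` never goes below 0, against a
#' chi-squared distribution with one degree of freedom.
#'
#' @param table 2 x 2 matrix of non-negative integer counts.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi2_yates <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(abs(table - round(table)) < 1e-9))
  # the chi-squared reference is the defined procedure even at small
  # expected counts, so the approximation warning is silenced
  ht <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Pearson correlation with t-based p value
#'
#' @param x,y paired numeric samples (n >= 3, non-constant).
#' @return List with `r`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant sample")
  ht <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Group summary statistics
#'
#' The per-genotype summary reported for every metric: n, mean, SD, SEM
#' (= SD / sqrt(n)), median and quartiles (the boxplot conventions: median
#' line, interquartile box, 1.5 x IQR whiskers).
#'
#' @param values numeric vector (NAs dropped).
#' @return One-row data frame with `n`, `mean`, `sd`, `sem`, `median`,
#'   `q1`, `q3`.
#' @export
group_summary <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  q <- if (n) stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE)
       else rep(NA_real_, 3)
  s <- if (n > 1) stats::sd(values) else NA_real_
  data.frame(n = n, mean = if (n) mean(values) else NA_real_,
             sd = s, sem = s / sqrt(n),
             median = q[2], q1 = q[1], q3 = q[3])
}
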