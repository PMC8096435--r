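# Contact angles, growth-rate fits, ellipse fitting, curve averaging and
# volume arithmetic.

#' Contact angle from a three-point annotation
#'
#' The compaction readout: the interior angle at the vertex (the contact
#' edge) between the two arms, in degrees. Invariant under rotation,
#' translation and uniform scaling of the points.
#'
#' @param points 3 x 2 numeric matrix, rows = (arm 1, vertex, arm 2) as
#'   (x, y).
#' @return Angle in degrees, in (0, 180].
#' @export
contact_angle <- function(points) {
  points <- as.matrix(points)
  stopifnot(is.numeric(points), all(dim(points) == c(3, 2)))
  v1 <- points[1, ] - points[2, ]
  v2 <- points[3, ] - points[2, ]
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 < 1e-12 || n2 < 1e-12) stop("vertex coincides with an arm point")
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  dot <- sum(v1 * v2)
  atan2(abs(cross), dot) * 180 / pi
}

#' Three-point annotation of a two-disk contact
#'
#' Builds the canonical three-point angle annotation for a synthetic embryo
#' of two equal contacting disks: the vertex is the upper intersection of
#' the circles and the arms lie a small arc away along each surface, going
#' away from the contact. As the arc length shrinks, [contact_angle()] on
#' these points converges to the closed-form surface angle
#' `2 * atan2(sqrt(r^2 - d^2/4), d/2)`.
#'
#' @param radius disk radius (um).
#' @param separation centre-to-centre distance, in `(0, 2 * radius)`.
#' @param arm_deg arc offset of the arm points, degrees.
#' @return 3 x 2 matrix (arm 1, vertex, arm 2) with attribute
#'   `"true_angle"` (degrees).
#' @export
two_disk_contact_points <- function(radius, separation, arm_deg = 2) {
  stopifnot(radius > 0, separation > 0, separation < 2 * radius)
  c_half <- separation / 2
  h <- sqrt(radius^2 - c_half^2)
  a1 <- atan2(h, c_half)            # vertex angle around the left centre
  d <- arm_deg * pi / 180
  p_vertex <- c(0, h)
  p_arm1 <- c(-c_half + radius * cos(a1 + d), radius * sin(a1 + d))
  p_arm2 <- c(c_half + radius * cos(pi - a1 - d), radius * sin(pi - a1 - d))
  out <- rbind(p_arm1, p_vertex, p_arm2)
  attr(out, "true_angle") <- 2 * atan2(h, c_half) * 180 / pi
  out
}

#' Post-lumen growth-rate fit
#'
#' Slope of projected area versus time over the window following lumen
#' opening (default 7 h), reported in um^2/min. The default estimator is
#' the OLS regression slope; `method = "endpoint"` uses the start-to-end
#' difference instead. Control embryos must grow by at least
#' `min_growth_fraction` of their starting area to pass the inclusion
#' filter; the filter does not apply to non-controls.
#'
#' @param time_h,area_um2 the area series of one embryo (t = 0 at lumen
#'   opening).
#' @param window_h fitting window, hours; the series must cover it.
#' @param min_growth_fraction minimal fractional area increase for control
#'   embryos.
#' @param is_control whether the growth filter applies.
#' @param method `"ols"` or `"endpoint"`.
#' @return List of class `growth_fit`: `rate_um2_min`, `window_h`,
#'   `fractional_increase`, `passes_filter`.
#' @export
growth_rate <- function(time_h, area_um2, window_h = 7,
                        min_growth_fraction = 0.35, is_control = TRUE,
                        method = c("ols", "endpoint")) {
  method <- match.arg(method)
  stopifnot(length(time_h) == length(area_um2), length(time_h) >= 2)
  if (max(time_h) < window_h) stop("series shorter than the fitting window")
  sel <- time_h >= 0 & time_h <= window_h + 1e-9
  t <- time_h[sel]; a <- area_um2[sel]
  slope_h <- if (method == "ols") {
    unname(stats::coef(stats::lm(a ~ t))[2])
  } else {
    (a[which.max(t)] - a[which.min(t)]) / (max(t) - min(t))
  }
  a_start <- a[which.min(t)]
  a_end <- a[which.max(t)]
  frac <- (a_end - a_start) / a_start
  structure(list(rate_um2_min = slope_h / 60,
                 window_h = window_h,
                 fractional_increase = frac,
                 passes_filter = !is_control || frac >= min_growth_fraction),
            class = "growth_fit")
}

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to an ellipse (Fitzgibbon's direct method in
#' the numerically stable two-block form) to at least six contour points,
#' e.g. the outer edge of the zona pellucida.
#'
#' @param points n x 2 matrix of (x, y) contour coordinates, n >= 6.
#' @return List of class `ellipse_fit`: `center`, `semi_major`,
#'   `semi_minor`, `orientation_deg` (major-axis angle), `aspect_ratio`
#'   (>= 1) and `area`.
#' @export
fit_ellipse <- function(points) {
  points <- as.matrix(points)
  stopifnot(is.numeric(points), ncol(points) == 2)
  if (nrow(points) < 6) stop("ellipse fit requires at least 6 points")
  mx <- mean(points[, 1]); my <- mean(points[, 2])
  x <- points[, 1] - mx; y <- points[, 2] - my
  d1 <- cbind(x^2, x * y, y^2)
  d2 <- cbind(x, y, 1)
  s1 <- crossprod(d1); s2 <- crossprod(d1, d2); s3 <- crossprod(d2)
  tmat <- tryCatch(-solve(s3, t(s2)), error = function(e) NULL)
  if (is.null(tmat)) stop("degenerate point configuration")
  mmat <- s1 + s2 %*% tmat
  mmat <- rbind(mmat[3, ] / 2, -mmat[2, ], mmat[1, ] / 2)
  eg <- eigen(mmat)
  cand <- Re(eg$vectors)
  cond <- 4 * cand[1, ] * cand[3, ] - cand[2, ]^2
  ok <- which(cond > 1e-12)
  if (!length(ok)) stop("no ellipse fits these points (degenerate input)")
  a1 <- cand[, ok[1]]
  coefs <- c(a1, tmat %*% a1)  # A B C D E F for centred coords
  A <- coefs[1]; B <- coefs[2]; C <- coefs[3]
  D <- coefs[4]; E <- coefs[5]; F <- coefs[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  num <- 2 * (A * E^2 + C * D^2 + F * B^2 - B * D * E - 4 * A * C * F)
  tt <- sqrt((A - C)^2 + B^2)
  ax1 <- -sqrt(num * ((A + C) + tt)) / den
  ax2 <- -sqrt(num * ((A + C) - tt)) / den
  semi_major <- max(ax1, ax2)
  semi_minor <- min(ax1, ax2)
  theta <- 0.5 * atan2(-B, C - A)
  if (ax1 < ax2) theta <- theta + pi / 2
  deg <- (theta * 180 / pi) %% 180
  if (180 - deg < 1e-6) deg <- 0
  structure(list(center = c(cx + mx, cy + my),
                 semi_major = semi_major, semi_minor = semi_minor,
                 orientation_deg = deg,
                 aspect_ratio = semi_major / semi_minor,
                 area = pi * semi_major * semi_minor),
            class = "ellipse_fit")
}

#' Synchronise and average area series
#'
#' Area series are already synchronised to lumen opening (t = 0); the mean
#' and SEM are computed pointwise on the hourly grid over the span common to
#' all embryos.
#'
#' @param series data frame with columns `embryo_id`, `time_h`, `area_um2`
#'   (e.g. from [make_area_series()]).
#' @return Data frame `time_h`, `mean_area`, `sem_area`, `n` on the common
#'   grid.
#' @export
sync_and_average <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("embryo_id", "time_h", "area_um2") %in% names(series)))
  ids <- unique(series$embryo_id)
  times <- Reduce(intersect, lapply(ids, function(id) {
    series$time_h[series$embryo_id == id]
  }))
  times <- sort(times)
  if (!length(times)) stop("series have no overlapping time points")
  rows <- lapply(times, function(t) {
    a <- series$area_um2[series$time_h == t]
    data.frame(time_h = t, mean_area = mean(a),
               sem_area = if (length(a) > 1) stats::sd(a) / sqrt(length(a)) else NA_real_,
               n = length(a))
  })
  do.call(rbind, rows)
}

#' Cellular volume of a blastocyst
#'
#' The cellular volume is the total segmented embryo volume minus the
#' blastocoel volume.
#'
#' @param total,blastocoel volumes in um^3 (vectorised);
#'   `0 <= blastocoel <= total`.
#' @return Cellular volume in um^3.
#' @export
cellular_volume <- function(total, blastocoel) {
  stopifnot(is.numeric(total), is.numeric(blastocoel))
  if (any(blastocoel < 0) || any(blastocoel > total)) {
    stop("blastocoel volume must lie in [0, total volume]")
  }
  total - blastocoel
}
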