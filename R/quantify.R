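# Immunostain and reporter quantification: N/C ratios, cell sampling,
# inner/outer classification, polarity line profiles, reporter intensity,
# and qPCR normalisation.

# Mean intensity in a circular ROI (centre in (x, y) pixel coordinates,
# area in um^2).
circle_mean <- function(image, center, pixel_size, roi_area_um2) {
  radius_px <- sqrt(roi_area_um2 / pi) / pixel_size
  nr <- nrow(image); nc <- ncol(image)
  x <- center[1]; y <- center[2]
  if (x - radius_px < 0.5 || x + radius_px > nc + 0.5 ||
      y - radius_px < 0.5 || y + radius_px > nr + 0.5) {
    stop("ROI extends outside the image")
  }
  m <- disc_mask(nr, nc, y, x, max(radius_px, 0.5))
  mean(image[m])
}

#' Nuclear-to-cytoplasmic intensity ratio
#'
#' Mean intensity in a circular ROI of area `roi_area_um2` (3.7 um^2 by
#' default, radius about 1.09 um) centred on the nucleus, divided by the
#' mean in an equal ROI at a directly adjacent cytoplasmic position. The
#' ratio is invariant under multiplicative intensity scaling but not under
#' additive offsets, matching the raw-intensity measurement it emulates.
#'
#' @param image numeric matrix (one channel, equatorial plane).
#' @param nucleus_center,cytoplasm_center ROI centres as (x, y) in pixels.
#' @param pixel_size um per pixel.
#' @param roi_area_um2 ROI area in um^2.
#' @return Nuclear / cytoplasmic mean-intensity ratio.
#' @export
nc_ratio <- function(image, nucleus_center, cytoplasm_center, pixel_size,
                     roi_area_um2 = 3.7) {
  nuc <- circle_mean(image, nucleus_center, pixel_size, roi_area_um2)
  cyt <- circle_mean(image, cytoplasm_center, pixel_size, roi_area_um2)
  if (cyt <= 0) stop("cytoplasmic signal is zero; ratio undefined")
  nuc / cyt
}

#' Select cells for intensity measurement
#'
#' The sampling rule for per-embryo fate quantification: five ICM, five
#' polar-TE and five mural-TE cells. If fewer than five ICM cells exist, a
#' corresponding number of TE cells is added instead; if the embryo has
#' fewer than 15 cells, all cells are selected. Selection within a class is
#' deterministic (by `cell_id` order).
#'
#' @param cells data frame with columns `cell_id` and `lineage_class`
#'   (`ICM`, `polar-TE`, `mural-TE`).
#' @param n_per_class target cells per class.
#' @return The selected subset of `cells`.
#' @export
sample_cells <- function(cells, n_per_class = 5) {
  stopifnot(is.data.frame(cells),
            all(c("cell_id", "lineage_class") %in% names(cells)))
  total_target <- 3 * n_per_class
  if (nrow(cells) <= total_target) return(cells)
  cells <- cells[order(cells$cell_id), ]
  icm <- cells[cells$lineage_class == "ICM", ]
  te <- cells[cells$lineage_class != "ICM", ]
  take_icm <- utils::head(icm, n_per_class)
  shortfall <- n_per_class - nrow(take_icm)
  pol <- te[te$lineage_class == "polar-TE", ]
  mur <- te[te$lineage_class == "mural-TE", ]
  take_pol <- utils::head(pol, n_per_class)
  take_mur <- utils::head(mur, n_per_class)
  extra_needed <- total_target - nrow(take_icm) - nrow(take_pol) - nrow(take_mur)
  taken <- c(take_icm$cell_id, take_pol$cell_id, take_mur$cell_id)
  if (extra_needed > 0) {
    pool <- te[!te$cell_id %in% taken, ]
    taken <- c(taken, utils::head(pool$cell_id, extra_needed))
  }
  cells[cells$cell_id %in% taken, ]
}

#' Inner/outer classification from cell masks
#'
#' A cell is an outer cell if it is in contact with the outside medium:
#' some pixel of its mask is 4-adjacent to a pixel outside the embryo mask.
#' All other cells are inner cells.
#'
#' @param labels integer matrix of cell labels (0 = no cell).
#' @param embryo_mask logical matrix of the embryo footprint; defaults to
#'   `labels > 0`.
#' @return Data frame `cell_id`, `position_class` plus attribute
#'   `"proportion_inner"`.
#' @export
classify_inner_outer <- function(labels, embryo_mask = NULL) {
  stopifnot(is.matrix(labels))
  if (is.null(embryo_mask)) embryo_mask <- labels > 0
  stopifnot(all(dim(embryo_mask) == dim(labels)))
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- embryo_mask
  outside <- !pad
  # dilate the exterior by one pixel (4-neighbourhood)
  touch <- outside[1:nr, 2:(nc + 1)] | outside[3:(nr + 2), 2:(nc + 1)] |
    outside[2:(nr + 1), 1:nc] | outside[2:(nr + 1), 3:(nc + 2)]
  ids <- sort(unique(labels[labels > 0]))
  outer_ids <- sort(unique(labels[labels > 0 & touch]))
  out <- data.frame(cell_id = ids,
                    position_class = ifelse(ids %in% outer_ids, "outer", "inner"))
  attr(out, "proportion_inner") <- mean(out$position_class == "inner")
  out
}

#' Apico-basal intensity line profile
#'
#' Samples intensity along a line of given length from a surface point into
#' the cell, averaging across the line thickness, then min-max normalises to
#' [0, 1]. A constant profile cannot be normalised and is returned as all
#' zeros with attribute `degenerate = TRUE`.
#'
#' @param image numeric matrix.
#' @param start (x, y) surface point in pixels.
#' @param direction (dx, dy) direction into the cell (any length).
#' @param pixel_size um per pixel.
#' @param length_um profile length (um).
#' @param thickness_um averaging thickness perpendicular to the line (um).
#' @param n_samples samples along the line.
#' @return Data frame of class `line_profile` with `distance_um` and
#'   `normalized_intensity`.
#' @export
line_profile <- function(image, start, direction, pixel_size,
                         length_um = 15, thickness_um = 0.4,
                         n_samples = 50) {
  stopifnot(length(start) == 2, length(direction) == 2)
  dn <- sqrt(sum(direction^2))
  if (dn < 1e-12) stop("zero direction vector")
  u <- direction / dn
  perp <- c(-u[2], u[1])
  dist <- seq(0, length_um, length.out = n_samples)
  offs <- seq(-thickness_um / 2, thickness_um / 2, length.out = 3)
  vals <- vapply(dist, function(s) {
    pts <- t(vapply(offs, function(o) {
      start + (s * u + o * perp) / pixel_size
    }, numeric(2)))
    if (any(pts[, 1] < 1 | pts[, 1] > ncol(image) |
            pts[, 2] < 1 | pts[, 2] > nrow(image))) {
      stop("profile line extends outside the image")
    }
    mean(interp_bilinear(image, pts[, 2], pts[, 1]))
  }, numeric(1))
  rng <- range(vals)
  degenerate <- diff(rng) < 1e-12
  norm <- if (degenerate) rep(0, length(vals)) else (vals - rng[1]) / diff(rng)
  out <- data.frame(distance_um = dist, normalized_intensity = norm)
  attr(out, "degenerate") <- degenerate
  class(out) <- c("line_profile", "data.frame")
  out
}

#' Background-corrected reporter intensity
#'
#' Mean gray value in a large circle over the embryo's sum projection minus
#' the mean in a small background circle. Use [normalize_to_reference()] to
#' express corrected intensities relative to the zygote-stage maternal mean.
#'
#' @param sum_projection numeric matrix (sum projection of the stack).
#' @param embryo_center,bg_center circle centres as (x, y) in pixels.
#' @param pixel_size um per pixel.
#' @param radius_um embryo circle radius (um).
#' @param bg_radius_um background circle radius (um).
#' @return Background-corrected mean intensity.
#' @export
reporter_intensity <- function(sum_projection, embryo_center, bg_center,
                               pixel_size, radius_um = 50, bg_radius_um = 5) {
  emb <- circle_mean(sum_projection, embryo_center, pixel_size,
                     pi * radius_um^2)
  bg <- circle_mean(sum_projection, bg_center, pixel_size,
                    pi * bg_radius_um^2)
  emb - bg
}

#' Normalise intensities to a reference group
#'
#' Divides corrected intensities by the mean of the reference group (e.g.
#' zygote-stage maternal reporter embryos), whose mean maps to 1.
#'
#' @param values corrected intensities.
#' @param reference_values the reference group's corrected intensities.
#' @return Normalised intensities.
#' @export
normalize_to_reference <- function(values, reference_values) {
  m <- mean(reference_values)
  if (!is.finite(m) || m == 0) stop("reference mean is zero or undefined")
  values / m
}

#' Relative expression by the 2^-dCT method
#'
#' Relative qPCR expression of a target gene normalised to a housekeeping
#' gene: `2^-(ct_target - ct_reference)`, optionally divided by a
#' calibrator (e.g. the zygote-stage level of a reference gene). Replicate
#' wells should be averaged on the CT scale before transformation (see
#' [average_ct()]). Strictly decreasing in `ct_target` and increasing in
#' `ct_reference`.
#'
#' @param ct_target,ct_reference CT values (vectorised).
#' @param calibrator normalised value of the calibrator condition.
#' @return Fold change.
#' @export
relative_expression <- function(ct_target, ct_reference, calibrator = 1) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)),
            all(calibrator > 0))
  2^-(ct_target - ct_reference) / calibrator
}

#' Average replicate CT values on the CT scale
#'
#' @param ct CT values of technical replicates.
#' @return Mean CT.
#' @export
average_ct <- function(ct) {
  stopifnot(all(is.finite(ct)))
  mean(ct)
}
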