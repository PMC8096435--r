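# Synthetic two-compartment (nucleus/cytoplasm) stain images with known
# intensity ratios and inner/outer ground truth.

#' Synthetic immunostain image with ground truth
#'
#' Renders an embryo as a disk partitioned into cells (Voronoi regions of
#' the cell centres within the disk), each with a circular nuclear
#' subregion whose intensity is `nc_ratio` times the cytoplasmic level.
#' Outer cells sit on a ring touching the embryo boundary; inner cells
#' (fraction `inner_fraction`) are placed strictly inside, surrounded by
#' the outer ring. ROI centres for [nc_ratio()] and the position-class
#' ground truth are emitted alongside the image.
#'
#' @param n_cells number of cells (>= 1).
#' @param nc_ratio nuclear/cytoplasmic intensity factor, scalar or one per
#'   cell (> 0).
#' @param inner_fraction fraction of cells rendered as inner cells.
#' @param pixel_size um per pixel.
#' @param cell_radius_um nominal cell radius (um).
#' @param cyto_intensity cytoplasmic intensity level.
#' @param noise_sd additive Gaussian noise (intensity units).
#' @param seed RNG seed.
#' @return A list of class `stain_stack`: `image` (matrix), `labels`
#'   (integer matrix), `embryo_mask`, `rois` (per-cell nucleus and
#'   cytoplasm sample points, px), `truth` (per-cell `position_class` and
#'   `nc_ratio`), `pixel_size`.
#' @export
make_stain_stack <- function(n_cells, nc_ratio = 2, inner_fraction = 0,
                             pixel_size = 0.5, cell_radius_um = 8,
                             cyto_intensity = 100, noise_sd = 0, seed = 1L) {
  stopifnot(n_cells >= 1, all(nc_ratio > 0),
            inner_fraction >= 0, inner_fraction <= 1)
  nc_ratio <- rep_len(nc_ratio, n_cells)
  n_inner <- if (n_cells == 1) 0L else as.integer(round(inner_fraction * n_cells))
  n_outer <- n_cells - n_inner
  if (n_inner > 0 && n_outer < 4) {
    stop("inner cells need at least 4 outer cells to enclose them")
  }
  r <- cell_radius_um
  # embryo radius: outer ring must hold n_outer cells of radius r
  R <- max(2 * r, r * (1 + n_outer / pi), 3.2 * r * (n_inner > 0))
  nr <- as.integer(ceiling(2 * (R + 2) / pixel_size))
  ctr <- (nr + 1) / 2
  # cell centres (um, relative to embryo centre)
  ang_out <- 2 * pi * (seq_len(n_outer) - 1) / max(n_outer, 1)
  centers <- cbind((R - r) * cos(ang_out), (R - r) * sin(ang_out))
  if (n_inner > 0) {
    ang_in <- 2 * pi * (seq_len(n_inner) - 1) / n_inner + pi / n_inner
    r_in <- min(R - 2.2 * r, R / 3)
    centers <- rbind(centers, cbind(r_in * cos(ang_in), r_in * sin(ang_in)))
  }
  truth_class <- c(rep("outer", n_outer), rep("inner", n_inner))
  if (n_cells == 1) centers <- matrix(0, 1, 2)

  xs <- (seq_len(nr) - ctr) * pixel_size
  X <- matrix(xs, nr, nr, byrow = TRUE)
  Y <- matrix(xs, nr, nr)
  inside <- X^2 + Y^2 <= R^2
  labels <- matrix(0L, nr, nr)
  # Voronoi assignment of embryo pixels to cell centres
  best <- (X - centers[1, 1])^2 + (Y - centers[1, 2])^2
  nearest <- matrix(1L, nr, nr)
  for (i in seq_len(n_cells)[-1]) {
    d <- (X - centers[i, 1])^2 + (Y - centers[i, 2])^2
    upd <- d < best
    nearest[upd] <- i
    best[upd] <- d[upd]
  }
  labels[inside] <- nearest[inside]

  nuc_r <- 0.35 * r
  image <- matrix(0, nr, nr)
  image[inside] <- cyto_intensity
  for (i in seq_len(n_cells)) {
    nuc <- (X - centers[i, 1])^2 + (Y - centers[i, 2])^2 <= nuc_r^2
    image[nuc & labels == i] <- cyto_intensity * nc_ratio[i]
  }
  if (noise_sd > 0) {
    image <- image + with_seed(seed, matrix(stats::rnorm(nr * nr, sd = noise_sd), nr, nr))
  }

  # ROI sample points: nucleus at the cell centre; cytoplasm adjacent,
  # along the radial direction (outward for outer cells, inward for inner
  # ones), which stays within the cell's own Voronoi region
  roi_rows <- lapply(seq_len(n_cells), function(i) {
    nrm <- sqrt(sum(centers[i, ]^2))
    dir <- if (nrm < 1e-9) c(1, 0) else centers[i, ] / nrm
    if (truth_class[i] == "inner") dir <- -dir
    cyto_um <- centers[i, ] + dir * (nuc_r + 1.6)
    data.frame(cell_id = i,
               nucleus_x = ctr + centers[i, 1] / pixel_size,
               nucleus_y = ctr + centers[i, 2] / pixel_size,
               cytoplasm_x = ctr + cyto_um[1] / pixel_size,
               cytoplasm_y = ctr + cyto_um[2] / pixel_size)
  })
  structure(list(image = image, labels = labels, embryo_mask = inside,
                 rois = do.call(rbind, roi_rows),
                 truth = data.frame(cell_id = seq_len(n_cells),
                                    position_class = truth_class,
                                    nc_ratio = nc_ratio),
                 pixel_size = pixel_size),
            class = "stain_stack")
}
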