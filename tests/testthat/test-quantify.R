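# Immunostain quantification: N/C ratios, sampling rule, inner/outer
# classification, line profiles, reporter intensity, qPCR normalisation.

test_that("N/C ratio behaves on uniform, synthetic and transformed images", {
  uni <- matrix(100, 60, 60)
  expect_equal(nc_ratio(uni, c(20, 20), c(40, 40), pixel_size = 0.5), 1)
  ss <- make_stain_stack(6, nc_ratio = 2, pixel_size = 0.5)
  r <- vapply(seq_len(6), function(i) {
    ro <- ss$rois[i, ]
    nc_ratio(ss$image, c(ro$nucleus_x, ro$nucleus_y),
             c(ro$cytoplasm_x, ro$cytoplasm_y), ss$pixel_size)
  }, 1)
  expect_equal(r, rep(2, 6), tolerance = 1e-9)
  # invariant under multiplicative scaling, not under additive offsets
  expect_equal(nc_ratio(ss$image * 7, c(ss$rois$nucleus_x[1], ss$rois$nucleus_y[1]),
                        c(ss$rois$cytoplasm_x[1], ss$rois$cytoplasm_y[1]), 0.5),
               r[1], tolerance = 1e-9)
  shifted <- nc_ratio(ss$image + 50, c(ss$rois$nucleus_x[1], ss$rois$nucleus_y[1]),
                      c(ss$rois$cytoplasm_x[1], ss$rois$cytoplasm_y[1]), 0.5)
  expect_false(isTRUE(all.equal(shifted, r[1])))
  # guards: off-image ROI and zero cytoplasmic signal
  expect_error(nc_ratio(uni, c(1, 1), c(40, 40), 0.5), "outside")
  zero <- matrix(0, 60, 60); zero[15:25, 15:25] <- 10
  expect_error(nc_ratio(zero, c(20, 20), c(45, 45), 0.5), "zero")
  # the 3.7-um^2 ROI has the analytic radius
  expect_equal(sqrt(3.7 / pi), 1.0852, tolerance = 1e-4)
})

test_that("cell sampling follows the 5+5+5 rule with TE replacement", {
  mk <- function(n_icm, n_pol, n_mur) {
    data.frame(cell_id = seq_len(n_icm + n_pol + n_mur),
               lineage_class = rep(c("ICM", "polar-TE", "mural-TE"),
                                   c(n_icm, n_pol, n_mur)))
  }
  # fewer than 15 cells: all measured
  expect_equal(nrow(sample_cells(mk(2, 3, 3))), 8)
  # balanced embryo: exactly 15, 5 per class
  s <- sample_cells(mk(10, 10, 10))
  expect_equal(nrow(s), 15)
  expect_equal(unname(table(s$lineage_class)["ICM"]), 5L)
  # ICM shortfall replaced by TE cells: 3 ICM + 12 TE
  s2 <- sample_cells(mk(3, 9, 9))
  expect_equal(nrow(s2), 15)
  expect_equal(sum(s2$lineage_class == "ICM"), 3)
  expect_equal(sum(s2$lineage_class != "ICM"), 12)
})

test_that("inner/outer classification matches medium contact and the truth", {
  # concentric construction: enclosed cell is inner
  lab <- matrix(0L, 40, 40)
  lab[blastoquant:::disc_mask(40, 40, 20, 20, 15)] <- 1L
  lab[blastoquant:::disc_mask(40, 40, 20, 20, 6)] <- 2L
  cl <- classify_inner_outer(lab)
  expect_equal(cl$position_class, c("outer", "inner"))
  expect_equal(attr(cl, "proportion_inner"), 0.5)
  # inner + outer always partitions the census
  ss <- make_stain_stack(20, nc_ratio = 2, inner_fraction = 0.3, pixel_size = 1)
  got <- classify_inner_outer(ss$labels, ss$embryo_mask)
  expect_equal(nrow(got), 20)
  expect_equal(sum(got$position_class == "inner"), 6)
  expect_equal(got$position_class, ss$truth$position_class)
  # merging one interior cell into another leaves every other class alone
  inner_ids <- got$cell_id[got$position_class == "inner"]
  lab2 <- ss$labels
  lab2[lab2 == inner_ids[1]] <- inner_ids[2]
  re <- classify_inner_outer(lab2, ss$embryo_mask)
  others <- got[!got$cell_id %in% inner_ids[1], ]
  expect_equal(re$position_class[match(others$cell_id, re$cell_id)],
               others$position_class)
})

test_that("line profiles normalise gradients and flag degenerate input", {
  grad <- matrix(rep(seq(0, 100, length.out = 80), each = 80), 80,
                 80)  # column j constant at value j: increases along x
  lp <- line_profile(grad, start = c(10, 40), direction = c(1, 0),
                     pixel_size = 0.5)
  expect_equal(lp$normalized_intensity[1], 0)
  expect_equal(tail(lp$normalized_intensity, 1), 1)
  expect_true(all(diff(lp$normalized_intensity) >= -1e-9))
  expect_equal(range(lp$normalized_intensity), c(0, 1))
  # constant image: degenerate, returned as zeros
  flat <- line_profile(matrix(7, 80, 80), c(10, 40), c(1, 0), 0.5)
  expect_true(attr(flat, "degenerate"))
  expect_equal(flat$normalized_intensity, rep(0, nrow(flat)))
  # synthetic basolateral marker: peak at the generated membrane depth
  img <- matrix(10, 80, 80)
  img[, 30:32] <- 200  # bright membrane ~10 um deep along the probe line
  lp2 <- line_profile(img, start = c(11, 40), direction = c(1, 0),
                      pixel_size = 0.5)
  expect_equal(lp2$distance_um[which.max(lp2$normalized_intensity)], 10,
               tolerance = 0.75)
  expect_error(line_profile(img, c(75, 40), c(1, 0), 0.5), "outside")
})

test_that("reporter intensity subtracts background and normalises to zygotes", {
  img <- matrix(50, 130, 130)
  img[blastoquant:::disc_mask(130, 130, 65, 65, 55)] <- 300
  corrected <- reporter_intensity(img, embryo_center = c(65, 65),
                                  bg_center = c(10, 10), pixel_size = 1)
  expect_equal(corrected, 250)
  # embryo equal to background: zero
  flat <- matrix(80, 130, 130)
  expect_equal(reporter_intensity(flat, c(65, 65), c(10, 10), 1), 0)
  # zygote group mean maps to 1
  zyg <- c(240, 260, 250)
  expect_equal(mean(normalize_to_reference(zyg, zyg)), 1)
  expect_equal(normalize_to_reference(corrected, zyg), 1)
})

test_that("relative expression follows 2^-dCT and its monotonicity", {
  expect_equal(relative_expression(12, 12), 1)
  expect_equal(relative_expression(14, 12), 0.25)
  expect_equal(relative_expression(11, 12), 2)
  # calibrator scaling
  expect_equal(relative_expression(12, 12, calibrator = 4), 0.25)
  # strictly decreasing in ct_target, increasing in ct_reference
  ct <- seq(8, 20, by = 0.5)
  expect_true(all(diff(relative_expression(ct, 15)) < 0))
  expect_true(all(diff(relative_expression(15, ct)) > 0))
  # replicates averaged on the CT scale first
  expect_equal(average_ct(c(20, 21, 22)), 21)
  expect_equal(relative_expression(average_ct(c(20, 22)), 20), 0.5)
})
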