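# Synthetic-data generators: movies, angle trajectories, timelines, area
# series, stain images. Every generator must be seed-reproducible and ship
# its ground truth.

test_that("static movie renders identical frames and respects validation", {
  spec <- synthetic_movie_spec(image_size = c(48, 48), n_frames = 4,
                               embryo_radius = 12, oscillation_period = 0,
                               oscillation_amplitude = 0, noise_sd = 0,
                               drift = c(0, 0), seed = 3)
  sm <- make_movie(spec)
  f <- sm$movie$frames
  expect_equal(f[, , 2], f[, , 1])
  expect_equal(f[, , 4], f[, , 1])
  expect_equal(sm$truth$radius_t, rep(12, 4))

  # Nyquist and geometry violations are refused
  expect_error(synthetic_movie_spec(frame_interval = 5, oscillation_period = 8),
               "Nyquist")
  expect_error(synthetic_movie_spec(image_size = c(64, 64), embryo_radius = 40),
               "exceeds the frame")
})

test_that("ten minutes at 5 s is 120 frames and the boundary radius carries the set period", {
  spec <- synthetic_movie_spec(n_frames = 10 * 60 / 5, oscillation_period = 80,
                               oscillation_amplitude = 2, noise_sd = 2, seed = 11)
  expect_identical(spec$n_frames, 120L)
  sm <- make_movie(spec)
  expect_equal(dim(sm$movie$frames)[3], 120)

  # measure the boundary radius per frame from the image, compare its DFT
  # peak with the analytic radius series (the oracle)
  px <- sm$movie$pixel_size
  r_meas <- apply(sm$movie$frames, 3, function(fr) sqrt(sum(fr > 300) * px^2 / pi))
  peak_bin <- function(x) {
    p <- Mod(fft(x - mean(x)))^2
    which.max(p[2:(length(x) %/% 2)])
  }
  expect_equal(peak_bin(r_meas), peak_bin(sm$truth$radius_t))
  # and that oracle peak corresponds to ~80 s on the DFT grid
  n <- length(r_meas)
  expect_equal(n * 5 / peak_bin(sm$truth$radius_t), 80, tolerance = 0.08)
})

test_that("generators are bit-reproducible and leave the caller RNG alone", {
  spec <- synthetic_movie_spec(image_size = c(32, 32), n_frames = 3,
                               embryo_radius = 8, seed = 5)
  set.seed(1234)
  before <- .Random.seed
  m1 <- make_movie(spec)
  expect_identical(.Random.seed, before)
  m2 <- make_movie(spec)
  expect_identical(m1$movie$frames, m2$movie$frames)

  p <- genotype_preset("WT")
  expect_identical(make_angle_series(p, 5, seed = 7),
                   make_angle_series(p, 5, seed = 7))
  expect_identical(summarize_timelines(make_timeline(p, 4, seed = 7)),
                   summarize_timelines(make_timeline(p, 4, seed = 7)))
  expect_identical(make_area_series(p, 3, seed = 7),
                   make_area_series(p, 3, seed = 7))
})

test_that("angle trajectories hit the preset plateaus", {
  p <- genotype_preset("WT")
  # noiseless cohort: every embryo ends exactly at the plateau
  a0 <- make_angle_series(p, 4, noise_sd = 0, embryo_sd = 0, seed = 1)
  expect_equal(a0$angle_deg[a0$stage_tag == "pre4th"], rep(147, 4))
  expect_equal(a0$angle_deg[a0$stage_tag == "post3rd"], rep(87, 4))
  # flat series when start equals end
  pf <- p; pf$angle_end <- pf$angle_start
  af <- make_angle_series(pf, 2, noise_sd = 0, embryo_sd = 0, seed = 1)
  expect_equal(af$angle_deg, rep(87, 8))
  # monotone non-decreasing ramp per embryo (noiseless)
  for (d in split(a0, a0$embryo_id)) {
    expect_true(all(diff(d$angle_deg[order(d$time_h)]) >= -1e-9))
  }
  # stochastic cohort at the study size recovers the plateau within 2 SEM
  a <- make_angle_series(p, 23, noise_sd = 5, seed = 1)
  expect_lt(abs(mean(a$angle_deg[a$stage_tag == "pre4th"]) - 147), 2 * 2)
  # ground truth is always attached
  expect_s3_class(attr(a, "truth"), "data.frame")
  expect_equal(nrow(attr(a, "truth")), 23)
})

test_that("timelines follow the cleavage model and its degenerate limits", {
  p <- genotype_preset("WT")
  # no failures, five waves: 2^5 cells
  tl <- make_timeline(p, 3, seed = 2)
  counts <- vapply(tl, final_cell_count, 1L)
  expect_equal(counts, rep(32L, 3))
  # all failures: single-celled embryo with the attempts on record
  pf <- genotype_preset("mzMyh9;mzMyh10")
  pf$division_failure_prob <- 1
  tlf <- make_timeline(pf, 2, seed = 2)
  for (t in tlf) {
    expect_equal(final_cell_count(t), 1L)
    expect_equal(sum(t$events$type == "failed_division"), 5)
    expect_equal(sum(t$events$type == "division"), 0)
  }
  # event times live on the 30-min grid
  times <- unlist(lapply(tl, function(t) t$events$time_h))
  expect_equal(times, round(times * 2) / 2)
  # simulated waves are recovered by the 30-min rule
  for (t in tl) {
    div <- t$events[t$events$type %in% c("division", "failed_division"), ]
    expect_equal(assign_waves(div$time_h), div$wave_truth)
  }
})

test_that("mzMyh9 timelines place some lumen openings before the fifth wave", {
  p <- genotype_preset("mzMyh9")
  tls <- make_timeline(p, 150, seed = 5)
  lead <- vapply(tls, function(t) {
    div <- t$events$time_h[t$events$type %in% c("division", "failed_division")]
    w <- assign_waves(sort(div))
    lum <- t$events$time_h[t$events$type == "lumen_open"]
    lum < min(sort(div)[w == 5])
  }, TRUE)
  # preset encodes the observed 5/11 fraction
  expect_lt(abs(mean(lead) - p$lumen_lead_prob), 0.1)
  # and WT never leads
  tlw <- make_timeline(genotype_preset("WT"), 30, seed = 5)
  leadw <- vapply(tlw, function(t) {
    div <- t$events$time_h[t$events$type %in% c("division", "failed_division")]
    w <- assign_waves(sort(div))
    t$events$time_h[t$events$type == "lumen_open"] < min(sort(div)[w == 5])
  }, TRUE)
  expect_false(any(leadw))
})

test_that("area series recover their growth rate", {
  p <- genotype_preset("WT")
  # noiseless: the OLS slope is the preset rate to machine precision
  pr <- p; pr$growth_rate_sem <- 0
  a0 <- make_area_series(pr, 2, noise_sd = 0, seed = 1)
  for (d in split(a0, a0$embryo_id)) {
    expect_equal(growth_rate(d$time_h, d$area_um2)$rate_um2_min, 3.9,
                 tolerance = 1e-10)
  }
  # zero growth rate fails the 35% control filter
  pz <- p; pz$growth_rate <- 0; pz$growth_rate_sem <- 0
  az <- make_area_series(pz, 1, noise_sd = 0, seed = 1)
  expect_false(growth_rate(az$time_h, az$area_um2, is_control = TRUE)$passes_filter)
  # study-sized cohort recovers the mean rate within 2 SEM
  a <- make_area_series(p, 20, seed = 1)
  rates <- vapply(split(a, a$embryo_id),
                  function(d) growth_rate(d$time_h, d$area_um2)$rate_um2_min, 1)
  expect_lt(abs(mean(rates) - 3.9), 2 * 0.5)
})

test_that("stain stacks carry coherent truth for ratios, counts and classes", {
  ss <- make_stain_stack(20, nc_ratio = 2, inner_fraction = 0.3, pixel_size = 1)
  expect_equal(sum(ss$truth$position_class == "inner"), 6)
  # label census equals the requested cell count
  ss58 <- make_stain_stack(58, nc_ratio = 1.5, pixel_size = 2)
  expect_equal(length(unique(ss58$labels[ss58$labels > 0])), 58)
  # unit ratio renders a flat embryo
  ss1 <- make_stain_stack(4, nc_ratio = 1, pixel_size = 1)
  expect_equal(length(unique(ss1$image[ss1$embryo_mask])), 1)
  # single cell touches the medium
  one <- make_stain_stack(1, nc_ratio = 2, pixel_size = 1)
  expect_equal(classify_inner_outer(one$labels, one$embryo_mask)$position_class,
               "outer")
})

test_that("movies round-trip through TIFF with calibration intact", {
  spec <- synthetic_movie_spec(image_size = c(32, 32), n_frames = 3,
                               embryo_radius = 8, seed = 9)
  sm <- make_movie(spec)
  path <- file.path(withr::local_tempdir(), "movie.tif")
  write_movie(sm$movie, path)
  back <- read_movie(path)
  expect_equal(back$pixel_size, sm$movie$pixel_size)
  expect_equal(back$frame_interval, sm$movie$frame_interval)
  # 16-bit quantisation only
  expect_lt(max(abs(back$frames - sm$movie$frames)) / max(sm$movie$frames), 1e-4)
})
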