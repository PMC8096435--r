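# Two-pass PIV: displacement recovery, invariances, masking.

test_that("rigid integer shifts are recovered exactly away from frame edges", {
  mv <- shifted_pair_movie(3, -2)
  msk <- interior_mask(96)
  vf <- piv_two_pass(mv, mask = msk)
  expect_lt(max(abs(vf$u[, 1] + 2)), 1e-6)
  expect_lt(max(abs(vf$v[, 1] - 3)), 1e-6)
  # brute-force full-frame cross-correlation agrees (the oracle)
  expect_equal(brute_force_shift(mv$frames[, , 1], mv$frames[, , 2]), c(3, -2))
})

test_that("subpixel shifts are recovered within 0.2 px on smooth texture", {
  tex <- make_speckle(96, sigma = 1.2, seed = 42)
  sh <- fourier_shift(tex, 0.5, 0.25)
  mv <- movie(array(c(tex, sh), dim = c(96, 96, 2)), 1, 1)
  vf <- piv_two_pass(mv, mask = interior_mask(96))
  expect_lt(abs(mean(vf$u[, 1]) - 0.25), 0.2)
  expect_lt(abs(mean(vf$v[, 1]) - 0.5), 0.2)
  # phase-correlation oracle on the full frame: the peak sits on one of the
  # lags bracketing the true (0.5, 0.25) shift
  xps <- Conj(fft(tex - mean(tex))) * fft(sh - mean(sh))
  ph <- Re(fft(xps / (Mod(xps) + 1e-12), inverse = TRUE))
  peak <- which(ph == max(ph), arr.ind = TRUE)[1, ]
  expect_true(peak["row"] %in% c(1, 2))  # lag 0 or 1 in y
  expect_true(peak["col"] %in% c(1, 2))  # lag 0 or 1 in x
})

test_that("static movies give zero velocities everywhere", {
  tex <- make_speckle(64)
  mv <- movie(array(rep(tex, 3), dim = c(64, 64, 3)), 1, 1)
  vf <- piv_two_pass(mv)
  expect_lt(max(abs(vf$u), abs(vf$v)), 1e-9)
  expect_true(all(vf$valid))
})

test_that("PIV is translation-equivariant and negates under frame swap", {
  big <- make_speckle(120, seed = 7)
  a <- big[13:108, 13:108]
  b <- big[11:106, 14:109]   # content moves +2 rows, -1 col
  a2 <- big[12:107, 12:107]  # both frames shifted by the same vector
  b2 <- big[10:105, 13:108]
  msk <- interior_mask(96)
  v1 <- piv_two_pass(movie(array(c(a, b), dim = c(96, 96, 2)), 1, 1), mask = msk)
  v2 <- piv_two_pass(movie(array(c(a2, b2), dim = c(96, 96, 2)), 1, 1), mask = msk)
  expect_equal(v1$u, v2$u, tolerance = 1e-6)
  expect_equal(v1$v, v2$v, tolerance = 1e-6)
  vs <- piv_two_pass(movie(array(c(b, a), dim = c(96, 96, 2)), 1, 1), mask = msk)
  expect_equal(vs$u, -v1$u, tolerance = 1e-6)
  expect_equal(vs$v, -v1$v, tolerance = 1e-6)
})

test_that("velocities come out in calibrated physical units", {
  mv <- shifted_pair_movie(2, 0)
  mv$pixel_size <- 0.5
  mv$frame_interval <- 4
  vf <- piv_two_pass(mv, window_pass1_um = 10, window_pass2_um = 5,
                     mask = interior_mask(96))
  expect_equal(unique(round(vf$v[, 1], 6)), 2 * 0.5 / 4)  # px * um/px / s
})

test_that("windows that are too small or too large are refused", {
  tex <- make_speckle(64)
  mv <- movie(array(rep(tex, 2), dim = c(64, 64, 2)), pixel_size = 2,
              frame_interval = 1)
  expect_error(piv_two_pass(mv, window_pass2_um = 6), "8 px")
  expect_error(piv_two_pass(mv, window_pass1_um = 400, window_pass2_um = 20),
               "larger than image")
  expect_error(piv_two_pass(movie(array(tex, dim = c(64, 64, 1)), 1, 1)),
               "at least 2 frames")
})

test_that("the embryo mask matches the disk and keeps the largest component", {
  sm <- make_movie(synthetic_movie_spec(image_size = c(100, 100), pixel_size = 1,
                                        n_frames = 3, embryo_radius = 30,
                                        oscillation_period = 0, seed = 21))
  msk <- mask_embryo(sm$movie)
  expect_lt(abs(sum(msk) - pi * 30^2) / (pi * 30^2), 0.1)
  # blank movie: empty mask, and PIV refuses it downstream
  blank <- movie(array(5, dim = c(64, 64, 2)), 1, 1)
  mb <- mask_embryo(blank)
  expect_false(any(mb))
  expect_error(piv_two_pass(blank, mask = mb), "no embryo")
  # two disks: only the largest survives
  img <- matrix(100, 100, 100)
  img[blastoquant:::disc_mask(100, 100, 30, 30, 18)] <- 500
  img[blastoquant:::disc_mask(100, 100, 75, 75, 8)] <- 500
  two <- movie(array(rep(img, 2), dim = c(100, 100, 2)), 1, 1)
  m2 <- mask_embryo(two)
  expect_true(m2[30, 30])
  expect_false(m2[75, 75])
  expect_lt(abs(sum(m2) - pi * 18^2) / (pi * 18^2), 0.15)
})

test_that("radially averaged PIV speed tracks the analytic boundary velocity", {
  spec <- synthetic_movie_spec(n_frames = 40, oscillation_period = 80,
                               oscillation_amplitude = 1.5, noise_sd = 2,
                               seed = 13)
  sm <- make_movie(spec)
  msk <- mask_embryo(sm$movie)
  vf <- piv_two_pass(sm$movie, mask = msk)
  # radial unit vectors at each vector position
  cx <- (128 + 1) / 2 * 0.7; cy <- cx
  rx <- vf$x - cx; ry <- vf$y - cy
  rn <- sqrt(rx^2 + ry^2)
  sel <- rn > 10  # radial direction ill-defined at the centre
  vr <- sweep(vf$u[sel, ], 1, rx[sel] / rn[sel], "*") +
    sweep(vf$v[sel, ], 1, ry[sel] / rn[sel], "*")
  mean_vr <- colMeans(vr)
  t_mid <- (seq_len(39) - 0.5) * 5
  # analytic boundary speed, scaled by the mean relative radius of the
  # probed positions (the deformation is a uniform dilation)
  drdt <- 1.5 * 2 * pi / 80 * cos(2 * pi * t_mid / 80)
  scale <- mean(rn[sel]) / 30
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(mean_vr - drdt * scale), 0.2 * rms(drdt * scale) + 0.01)
})
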