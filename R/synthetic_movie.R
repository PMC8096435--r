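#' Specification of a synthetic contraction movie
#'
#' Describes a speckle-textured disk-shaped embryo whose cortex undergoes
#' periodic radial deformation, `r(t) = R + A * sin(2 * pi * t / T)`, plus an
#' optional rigid drift and additive Gaussian noise. These movies feed the
#' PIV and spectral stages with a known ground truth.
#'
#' @param image_size frame size in pixels, `c(H, W)`.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval seconds between frames (5 s emulates the
#'   short-timescale acquisitions).
#' @param n_frames number of frames (120 frames at 5 s is a 10-min record).
#' @param embryo_radius mean embryo radius in micrometres.
#' @param oscillation_period contraction period in seconds; 0 disables the
#'   oscillation. Must exceed twice the frame interval (Nyquist).
#' @param oscillation_amplitude radial peak deformation in micrometres.
#' @param texture_grain speckle correlation length in micrometres.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (intensity units; the embryo interior spans roughly 250-750).
#' @param drift rigid drift in micrometres per frame, `c(dx, dy)`.
#' @param seed RNG seed; equal seeds give bit-identical movies.
#' @return A validated list of class `synthetic_movie_spec`.
#' @export
synthetic_movie_spec <- function(image_size = c(128, 128),
                                 pixel_size = 0.7,
                                 frame_interval = 5,
                                 n_frames = 120,
                                 embryo_radius = 30,
                                 oscillation_period = 80,
                                 oscillation_amplitude = 1,
                                 texture_grain = 1,
                                 noise_sd = 5,
                                 drift = c(0, 0),
                                 seed = 1L) {
  spec <- list(image_size = as.integer(image_size), pixel_size = pixel_size,
               frame_interval = frame_interval, n_frames = as.integer(n_frames),
               embryo_radius = embryo_radius,
               oscillation_period = oscillation_period,
               oscillation_amplitude = oscillation_amplitude,
               texture_grain = texture_grain, noise_sd = noise_sd,
               drift = drift, seed = as.integer(seed))
  stopifnot(length(spec$image_size) == 2, all(spec$image_size >= 16),
            spec$pixel_size > 0, spec$frame_interval > 0, spec$n_frames >= 1,
            spec$embryo_radius > 0, spec$oscillation_amplitude >= 0,
            spec$texture_grain > 0, spec$noise_sd >= 0, length(spec$drift) == 2)
  if (spec$oscillation_period != 0 &&
      spec$oscillation_period <= 2 * spec$frame_interval) {
    stop("oscillation_period violates Nyquist: must be 0 or > 2 * frame_interval")
  }
  max_r <- spec$embryo_radius + spec$oscillation_amplitude
  max_shift <- max(abs(spec$drift)) * (spec$n_frames - 1)
  half_field <- min(spec$image_size) / 2 * spec$pixel_size
  if (max_r + max_shift + 2 * spec$pixel_size > half_field) {
    stop("embryo exceeds the frame at maximal deformation/drift")
  }
  structure(spec, class = "synthetic_movie_spec")
}

#' Render a synthetic contraction movie
#'
#' Generates a band-pass speckle texture, maps it onto a disk whose radius
#' follows the prescribed sinusoid, advects the texture with the radial
#' deformation (uniform dilation, so the speckle tracks the local boundary)
#' and adds drift and Gaussian noise. The ground truth is returned alongside
#' the movie.
#'
#' @param spec a [synthetic_movie_spec()].
#' @return A list of class `synthetic_movie` with elements `movie` (a
#'   [movie()]) and `truth` (period, amplitude, radius, drift, and the
#'   per-frame boundary radius `radius_t` in micrometres).
#' @export
make_movie <- function(spec) {
  stopifnot(inherits(spec, "synthetic_movie_spec"))
  H <- spec$image_size[1]; W <- spec$image_size[2]
  px <- spec$pixel_size
  times <- (seq_len(spec$n_frames) - 1) * spec$frame_interval
  r_t <- if (spec$oscillation_period == 0) {
    rep(spec$embryo_radius, spec$n_frames)
  } else {
    spec$embryo_radius +
      spec$oscillation_amplitude * sin(2 * pi * times / spec$oscillation_period)
  }
  cy0 <- (H + 1) / 2
  cx0 <- (W + 1) / 2
  grain_px <- spec$texture_grain / px
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)

  frames <- with_seed(spec$seed, {
    tex <- matrix(stats::rnorm(H * W), H, W)
    tex <- fft_gauss_blur(tex, grain_px)
    tex <- tex - fft_gauss_blur(tex, 4 * grain_px)  # band-pass speckle
    tex <- tex / stats::sd(tex)
    out <- array(0, dim = c(H, W, spec$n_frames))
    for (t in seq_len(spec$n_frames)) {
      cy <- cy0 + (t - 1) * spec$drift[2] / px
      cx <- cx0 + (t - 1) * spec$drift[1] / px
      dy <- rows - cy
      dx <- cols - cx
      rho <- sqrt(dy^2 + dx^2) * px  # um from current centre
      scale <- spec$embryo_radius / r_t[t]
      val <- interp_bilinear(tex, cy0 + dy * scale, cx0 + dx * scale)
      edge <- 1 / (1 + exp((rho - r_t[t]) / 0.5))  # 0.5-um soft edge
      img <- 100 + edge * (400 + 150 * val)
      if (spec$noise_sd > 0) img <- img + stats::rnorm(H * W, sd = spec$noise_sd)
      out[, , t] <- pmax(img, 0)
    }
    out
  })
  structure(list(
    movie = movie(frames, px, spec$frame_interval),
    truth = list(period = spec$oscillation_period,
                 amplitude = spec$oscillation_amplitude,
                 radius = spec$embryo_radius,
                 drift = spec$drift,
                 radius_t = r_t)),
    class = "synthetic_movie")
}
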