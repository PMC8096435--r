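#' Calibrated image stack
#'
#' A movie is the raw substrate of PIV and morphometrics: a stack of 2D
#' frames with a spatial calibration (micrometres per pixel) and a temporal
#' calibration (seconds between frames).
#'
#' @param frames numeric array of dimension H x W x T (rows, columns, frames),
#'   or a list of equally sized matrices.
#' @param pixel_size pixel size in micrometres per pixel (> 0).
#' @param frame_interval time between consecutive frames in seconds (> 0).
#' @return An object of class `movie`: a list with elements `frames`
#'   (H x W x T array), `pixel_size` and `frame_interval`.
#' @export
movie <- function(frames, pixel_size, frame_interval) {
  if (is.list(frames)) {
    frames <- simplify2array(frames)
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (dim(frames)[3] < 1) stop("movie must contain at least one frame")
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(frame_interval), frame_interval > 0)
  structure(list(frames = frames,
                 pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<movie> %d frames of %d x %d px (%.3g um/px, %.3g s/frame)\n",
              d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

n_frames <- function(m) dim(m$frames)[3]

sidecar_path <- function(path) paste0(path, ".yaml")

#' Write a movie to a multi-page TIFF
#'
#' Frames are written as 16-bit greyscale pages. TIFF cannot carry the
#' physical calibration portably, so `pixel_size`, `frame_interval` and the
#' intensity scale are written to a YAML sidecar (`<path>.yaml`) that
#' [read_movie()] consumes.
#'
#' @param m a [movie()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "movie"))
  hi <- max(m$frames, 1e-12)
  scaled <- lapply(seq_len(n_frames(m)), function(t) {
    pmin(pmax(m$frames[, , t] / hi, 0), 1)
  })
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L, reduce = FALSE)
  yaml::write_yaml(list(pixel_size = m$pixel_size,
                        frame_interval = m$frame_interval,
                        intensity_scale = hi),
                   sidecar_path(path))
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path; the YAML sidecar written alongside is required
#'   unless both calibrations are supplied explicitly.
#' @param pixel_size,frame_interval optional calibration overrides.
#' @return A [movie()].
#' @export
read_movie <- function(path, pixel_size = NULL, frame_interval = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  meta <- if (file.exists(sidecar_path(path))) {
    yaml::read_yaml(sidecar_path(path))
  } else {
    list()
  }
  pixel_size <- pixel_size %||% meta$pixel_size
  frame_interval <- frame_interval %||% meta$frame_interval
  if (is.null(pixel_size) || is.null(frame_interval)) {
    stop("pixel_size and frame_interval must come from the sidecar or arguments")
  }
  scale <- meta$intensity_scale %||% 1
  frames <- simplify2array(lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * scale
  }))
  movie(frames, pixel_size, frame_interval)
}
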