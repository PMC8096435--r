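# Cleavage-wave assignment, stage durations, lumen timing and cell-count
# bookkeeping on embryo event timelines.

#' Embryo event timeline
#'
#' An annotated (or simulated) record of division events, failed cytokineses,
#' reverting cleavages and morphogenetic events on a common 30-min clock.
#' All timings are conventionally normalised to `t0`, the end of the third
#' cleavage wave.
#'
#' @param events data frame with columns `time_h` (hours), `type` (one of
#'   `division`, `failed_division`, `fusion_reversion`, `lumen_open`,
#'   `max_compaction`) and optionally `cell_id`.
#' @param embryo_id embryo label.
#' @param t0 reference time (end of the third cleavage wave), hours. If
#'   `NULL` it is computed from the division events via [assign_waves()].
#' @param start_count cell count before the first recorded event.
#' @return An object of class `embryo_timeline`.
#' @export
embryo_timeline <- function(events, embryo_id = "embryo", t0 = NULL,
                            start_count = 1L) {
  stopifnot(is.data.frame(events),
            all(c("time_h", "type") %in% names(events)))
  valid_types <- c("division", "failed_division", "fusion_reversion",
                   "lumen_open", "max_compaction")
  bad <- setdiff(unique(events$type), valid_types)
  if (length(bad)) stop("unknown event types: ", paste(bad, collapse = ", "))
  events <- events[order(events$time_h), , drop = FALSE]
  rownames(events) <- NULL
  tl <- structure(list(embryo_id = embryo_id, events = events, t0 = t0,
                       start_count = as.integer(start_count)),
                  class = "embryo_timeline")
  if (is.null(t0)) {
    dt <- division_times(tl)
    if (length(dt)) {
      w <- assign_waves(dt)
      if (max(w) >= 3) tl$t0 <- max(dt[w == 3])
    }
  }
  tl
}

#' @export
print.embryo_timeline <- function(x, ...) {
  cat(sprintf("<embryo_timeline> %s: %d events, final count %d\n",
              x$embryo_id, nrow(x$events), final_cell_count(x)))
  invisible(x)
}

# Division and failed-division times (failed cytokinesis counts as part of
# cleavage waves).
division_times <- function(timeline) {
  ev <- timeline$events
  sort(ev$time_h[ev$type %in% c("division", "failed_division")])
}

#' Assign cleavage divisions to waves
#'
#' Divisions belong to the same wave when they occur within 30 min of the
#' division of another cell of the same embryo. This is read as transitive
#' (single-linkage) chaining: after sorting, a gap greater than `gap_h`
#' between consecutive divisions starts a new wave. The rule is inclusive
#' (a gap of exactly 30 min keeps the same wave), depends only on the time
#' multiset, and is idempotent.
#'
#' @param times_h division times in hours (any order).
#' @param gap_h chaining gap, hours (30 min by default).
#' @return Integer wave labels aligned with `times_h`; `integer(0)` for
#'   empty input.
#' @export
assign_waves <- function(times_h, gap_h = 0.5) {
  if (!length(times_h)) return(integer(0))
  stopifnot(is.numeric(times_h), all(is.finite(times_h)), gap_h > 0)
  ord <- order(times_h)
  st <- times_h[ord]
  lab <- cumsum(c(1L, as.integer(diff(st) > gap_h + 1e-9)))
  out <- integer(length(times_h))
  out[ord] <- lab
  out
}

#' Duration between two cleavage waves
#'
#' The 8-cell-stage duration is the time from the last division of the third
#' wave to the first division of the fourth wave; generically, from the last
#' event of `from_wave` to the first event of `to_wave`. Failed cytokineses
#' count as wave members.
#'
#' @param timeline an [embryo_timeline()].
#' @param from_wave,to_wave wave numbers.
#' @return Duration in hours, or `NA_real_` if either wave is absent.
#' @export
stage_duration <- function(timeline, from_wave = 3, to_wave = 4) {
  stopifnot(inherits(timeline, "embryo_timeline"))
  dt <- division_times(timeline)
  if (!length(dt)) return(NA_real_)
  w <- assign_waves(dt)
  if (!(from_wave %in% w) || !(to_wave %in% w)) return(NA_real_)
  min(dt[w == to_wave]) - max(dt[w == from_wave])
}

#' Time of lumen opening
#'
#' Lumen opening is called when a fluid compartment of diameter at least
#' `diameter_um` is visible. For a timeline this is the recorded
#' `lumen_open` event; for an annotated diameter series it is the first time
#' the threshold is reached. Times are normalised to the timeline's `t0`
#' when available.
#'
#' @param x an [embryo_timeline()], or a data frame with columns `time_h`
#'   and `diameter_um`.
#' @param diameter_um lumen-diameter threshold in micrometres.
#' @param normalize subtract `t0` (timelines only).
#' @return Time in hours, or `NA_real_` if the criterion is never met.
#' @export
lumen_time <- function(x, diameter_um = 20, normalize = TRUE) {
  if (inherits(x, "embryo_timeline")) {
    t <- x$events$time_h[x$events$type == "lumen_open"]
    if (!length(t)) return(NA_real_)
    t <- min(t)
    if (normalize && !is.null(x$t0)) t <- t - x$t0
    return(t)
  }
  stopifnot(is.data.frame(x), all(c("time_h", "diameter_um") %in% names(x)))
  hit <- which(x$diameter_um >= diameter_um)
  if (!length(hit)) return(NA_real_) else x$time_h[min(hit)]
}

#' Final cell count of a timeline
#'
#' Starting from `start_count`, each successful division adds one cell and
#' each reverting cleavage removes one; failed cytokineses leave the count
#' unchanged (their attempts remain on record). The count never drops below
#' one.
#'
#' @param timeline an [embryo_timeline()].
#' @return Integer cell count.
#' @export
final_cell_count <- function(timeline) {
  stopifnot(inherits(timeline, "embryo_timeline"))
  ev <- timeline$events
  n <- timeline$start_count + sum(ev$type == "division") -
    sum(ev$type == "fusion_reversion")
  max(n, 1L)
}

#' Normalise event times to the end of the third cleavage
#'
#' @param timeline an [embryo_timeline()] with a defined `t0`.
#' @return The timeline with `time_h` shifted so the end of the third
#'   cleavage wave is 0 (and `t0` set to 0).
#' @export
normalize_timeline <- function(timeline) {
  stopifnot(inherits(timeline, "embryo_timeline"))
  if (is.null(timeline$t0)) stop("timeline has no t0 (third wave absent)")
  timeline$events$time_h <- timeline$events$time_h - timeline$t0
  timeline$t0 <- 0
  timeline
}

#' Time and value of maximal compaction
#'
#' Maximal compaction is when the embryo stops increasing its contact
#' angles: the argmax of the (optionally smoothed) angle series, with
#' plateau ties broken to the earliest time.
#'
#' @param time_h,angle_deg the angle series of one embryo.
#' @param smooth_k odd running-mean window (1 = none; the default, as the
#'   canonical series has only four points).
#' @return List with `time_h` and `angle_deg` at maximal compaction.
#' @export
max_compaction <- function(time_h, angle_deg, smooth_k = 1) {
  stopifnot(length(time_h) == length(angle_deg), length(time_h) >= 1)
  ord <- order(time_h)
  t <- time_h[ord]; a <- angle_deg[ord]
  if (smooth_k > 1) {
    a <- stats::filter(a, rep(1 / smooth_k, smooth_k), sides = 2)
    keep <- !is.na(a)
    t <- t[keep]; a <- as.numeric(a[keep])
  }
  i <- which.max(a)  # which.max takes the earliest tie
  list(time_h = t[i], angle_deg = a[i])
}

#' Per-embryo event summary of a timeline cohort
#'
#' @param cohort a list of [embryo_timeline()] objects (e.g. from
#'   [make_timeline()]).
#' @return Data frame with one row per embryo: 8-cell-stage duration,
#'   normalised lumen time, and final cell count.
#' @export
summarize_timelines <- function(cohort) {
  rows <- lapply(cohort, function(tl) {
    data.frame(embryo_id = tl$embryo_id,
               stage8_duration_h = stage_duration(tl, 3, 4),
               lumen_time_h = lumen_time(tl),
               final_cell_count = final_cell_count(tl))
  })
  do.call(rbind, rows)
}
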