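# Synthetic cohorts: compaction angle trajectories, cleavage-event
# timelines, and post-lumen projected-area series, one per genotype preset.
# Every generator returns its ground truth alongside the data.

# Logistic ramp rescaled to hit `from` exactly at t = 0 and `to` exactly at
# t = duration; flat at `to` afterwards. Compaction curves are sigmoidal but
# no functional form is canonical, so a normalised logistic is used.
angle_ramp <- function(t, from, to, duration, steepness = 10) {
  s <- function(z) 1 / (1 + exp(-z))
  tt <- pmin(pmax(t, 0), duration)
  raw <- s(steepness * (tt / duration - 0.5))
  lo <- s(-steepness / 2)
  hi <- s(steepness / 2)
  from + (to - from) * (raw - lo) / (hi - lo)
}

#' Synthetic compaction angle trajectories
#'
#' Generates per-embryo contact-angle series sampled at the four stages used
#' for compaction scoring: after the third cleavage (t = 0), just before the
#' fourth cleavage (t = 8-cell-stage duration), after the fourth cleavage and
#' just before the fifth. Each embryo ramps logistically between its own
#' start and plateau angles; embryo-level parameters are drawn around the
#' preset means with spread `SEM * sqrt(n)`, and i.i.d. measurement noise is
#' added at each sampling point.
#'
#' @param preset a [genotype_preset()].
#' @param n_embryos cohort size (>= 1).
#' @param noise_sd per-measurement angle noise, degrees.
#' @param embryo_sd between-embryo spread of the plateau angle, degrees;
#'   defaults to the preset's `angle_end_sem * sqrt(n_angle)`. Set 0 (with
#'   `noise_sd = 0`) for a fully deterministic cohort.
#' @param seed RNG seed.
#' @return A data frame with columns `embryo_id`, `stage_tag`
#'   (`post3rd`/`pre4th`/`post4th`/`pre5th`), `time_h`, `angle_deg`, plus a
#'   `"truth"` attribute (per-embryo start, plateau and ramp duration).
#' @export
make_angle_series <- function(preset, n_embryos, noise_sd = 2,
                              embryo_sd = NULL, seed = 1L) {
  stopifnot(inherits(preset, "genotype_preset"), n_embryos >= 1, noise_sd >= 0)
  sds <- preset_sds(preset)
  if (is.null(embryo_sd)) embryo_sd <- sds$angle_end
  start_sd <- if (embryo_sd == 0) 0 else sds$angle_start
  dur_sd <- if (embryo_sd == 0) 0 else sds$stage8
  with_seed(seed, {
    start_i <- stats::rnorm(n_embryos, preset$angle_start, start_sd)
    end_i <- stats::rnorm(n_embryos, preset$angle_end, embryo_sd)
    dur_i <- pmax(stats::rnorm(n_embryos, preset$stage8_duration, dur_sd), 1)
    tags <- c("post3rd", "pre4th", "post4th", "pre5th")
    rows <- lapply(seq_len(n_embryos), function(i) {
      t_i <- c(0, dur_i[i], dur_i[i] + 0.75, dur_i[i] + 9)
      ang <- angle_ramp(t_i, start_i[i], end_i[i], dur_i[i]) +
        stats::rnorm(4, sd = noise_sd)
      data.frame(embryo_id = sprintf("%s_%02d", preset$name, i),
                 stage_tag = tags, time_h = t_i,
                 angle_deg = pmin(pmax(ang, 1), 179))
    })
    out <- do.call(rbind, rows)
    out$stage_tag <- factor(out$stage_tag, levels = tags)
    attr(out, "truth") <- data.frame(
      embryo_id = sprintf("%s_%02d", preset$name, seq_len(n_embryos)),
      angle_start = start_i, angle_end = end_i, duration_h = dur_i)
    out
  })
}

#' Synthetic cleavage-event timelines
#'
#' Simulates five cleavage waves per embryo on a 30-min sampling grid. Every
#' cell attempts cytokinesis in every wave; each attempt fails independently
#' with the preset's `division_failure_prob` (failed attempts are recorded
#' and counted as wave members, but do not increment the cell count).
#' Intra-wave divisions are jittered within 25 min so the 30-min wave rule
#' groups them by construction. The gap between the last third-wave and
#' first fourth-wave division is the embryo's 8-cell-stage duration, drawn
#' around the preset mean with spread `SEM * sqrt(n)`; the other inter-wave
#' gaps use `wave_gap_h`. A lumen-opening event follows the fifth wave,
#' except with probability `lumen_lead_prob` it precedes it.
#'
#' @param preset a [genotype_preset()].
#' @param n_embryos cohort size (>= 1).
#' @param seed RNG seed.
#' @param n_waves number of cleavage waves to simulate.
#' @param wave_gap_h default gap between consecutive waves, hours (the
#'   8-cell-stage gap comes from the preset instead).
#' @return A list of [embryo_timeline()] objects (class `timeline_cohort`)
#'   with a `"truth"` attribute (per-embryo 8-cell duration, failure
#'   probability, wave anchor times).
#' @export
make_timeline <- function(preset, n_embryos, seed = 1L, n_waves = 5,
                          wave_gap_h = 10) {
  stopifnot(inherits(preset, "genotype_preset"), n_embryos >= 1, n_waves >= 1)
  sds <- preset_sds(preset)
  p_fail <- preset$division_failure_prob
  snap <- function(t) round(t * 2) / 2  # 30-min grid
  with_seed(seed, {
    stage8_i <- pmax(stats::rnorm(n_embryos, preset$stage8_duration, sds$stage8), 2)
    lead_i <- stats::runif(n_embryos) < (preset$lumen_lead_prob %||% 0)
    timelines <- vector("list", n_embryos)
    truth <- data.frame(embryo_id = character(n_embryos),
                        stage8_duration = stage8_i,
                        division_failure_prob = p_fail,
                        final_cell_count = NA_integer_)
    for (i in seq_len(n_embryos)) {
      id <- sprintf("%s_%02d", preset$name, i)
      cells <- 1L
      next_id <- 2L
      cell_ids <- 1L
      start_wave <- 0
      wave_starts <- numeric(n_waves)
      ev_time <- numeric(0); ev_type <- character(0)
      ev_cell <- integer(0); ev_wave <- integer(0)
      t0 <- NA_real_
      for (w in seq_len(n_waves)) {
        wave_starts[w] <- start_wave
        jit <- c(0, stats::runif(max(cells - 1L, 0), 0, 25 / 60))
        att_t <- start_wave + jit
        ok <- stats::runif(cells) >= p_fail
        new_ids <- integer(0)
        for (k in seq_len(cells)) {
          ev_time <- c(ev_time, snap(att_t[k]))
          ev_type <- c(ev_type, if (ok[k]) "division" else "failed_division")
          ev_cell <- c(ev_cell, cell_ids[k])
          ev_wave <- c(ev_wave, w)
          if (ok[k]) {
            new_ids <- c(new_ids, next_id)
            next_id <- next_id + 1L
          }
        }
        cell_ids <- c(cell_ids, new_ids)
        cells <- cells + length(new_ids)
        wave_end <- max(att_t)
        if (w == 3) t0 <- snap(wave_end)
        gap <- if (w == 3) stage8_i[i] else wave_gap_h
        start_wave <- wave_end + gap
      }
      lumen_t <- if (lead_i[i]) wave_starts[n_waves] - 1 else max(ev_time) + 1.5
      ev_time <- c(ev_time, snap(lumen_t))
      ev_type <- c(ev_type, "lumen_open")
      ev_cell <- c(ev_cell, NA_integer_)
      ev_wave <- c(ev_wave, NA_integer_)
      events <- data.frame(time_h = ev_time, type = ev_type,
                           cell_id = ev_cell, wave_truth = ev_wave)
      events <- events[order(events$time_h), ]
      timelines[[i]] <- embryo_timeline(events, embryo_id = id, t0 = t0)
      truth$embryo_id[i] <- id
      truth$final_cell_count[i] <- cells
    }
    structure(timelines, class = "timeline_cohort", truth = truth)
  })
}

#' Synthetic post-lumen projected-area series
#'
#' Hourly projected areas starting at lumen opening, growing linearly at the
#' preset rate (converted from um^2/min to um^2/h) with per-embryo rate
#' variation (`SEM * sqrt(n)`) and additive measurement noise.
#'
#' @param preset a [genotype_preset()].
#' @param n_embryos cohort size.
#' @param hours span of the series in hours (>= 7 so the 7-h growth window
#'   is covered).
#' @param noise_sd per-measurement area noise, um^2.
#' @param area0 projected area at lumen opening, um^2.
#' @param seed RNG seed.
#' @return A data frame `embryo_id`, `time_h`, `area_um2` with a `"truth"`
#'   attribute holding each embryo's true rate in um^2/min.
#' @export
make_area_series <- function(preset, n_embryos, hours = 7, noise_sd = 50,
                             area0 = 4000, seed = 1L) {
  stopifnot(inherits(preset, "genotype_preset"), n_embryos >= 1, hours >= 7)
  sds <- preset_sds(preset)
  with_seed(seed, {
    rate_i <- stats::rnorm(n_embryos, preset$growth_rate, sds$growth_rate)
    rows <- lapply(seq_len(n_embryos), function(i) {
      t <- 0:hours
      area <- area0 + rate_i[i] * 60 * t + stats::rnorm(length(t), sd = noise_sd)
      data.frame(embryo_id = sprintf("%s_%02d", preset$name, i),
                 time_h = t, area_um2 = area)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- data.frame(
      embryo_id = sprintf("%s_%02d", preset$name, seq_len(n_embryos)),
      rate_um2_min = rate_i)
    out
  })
}
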