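# Pipeline orchestration: configuration, deterministic cohort analysis and
# per-stage CSV/JSON output.

#' Pipeline run configuration
#'
#' Aggregates the method constants (all overridable, none hard-coded
#' downstream): the oscillation band and threshold, PIV windows, growth
#' window and filter, wave-chaining gap and lumen-diameter criterion,
#' together with the genotype preset, cohort size and seed.
#'
#' @param genotype preset name (see [genotype_presets()]).
#' @param n_embryos cohort size; defaults to the preset's recorded cohort
#'   size.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param out_dir output directory for CSVs and the manifest.
#' @param band,threshold oscillation call parameters (s, ratio).
#' @param window_pass1_um,window_pass2_um PIV interrogation windows (um).
#' @param growth_window_h,growth_min_fraction growth fit window (h) and
#'   control filter.
#' @param wave_gap_h cleavage-wave chaining gap (h).
#' @param lumen_diameter_um lumen-opening diameter criterion (um).
#' @param n_movies synthetic short-timescale movies to run through
#'   PIV/spectral (kept small; each movie is the costly stage).
#' @param movie_frames frames per synthetic movie.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(genotype = "WT", n_embryos = NULL, seed = 1L,
                       out_dir = tempfile("blastoquant_run_"),
                       band = c(50, 120), threshold = 1.7,
                       window_pass1_um = 20, window_pass2_um = 10,
                       growth_window_h = 7, growth_min_fraction = 0.35,
                       wave_gap_h = 0.5, lumen_diameter_um = 20,
                       n_movies = 2, movie_frames = 120) {
  preset <- genotype_preset(genotype)
  n_embryos <- n_embryos %||% (preset$n_timeline %||% 10)
  cfg <- list(genotype = genotype, n_embryos = as.integer(n_embryos),
              seed = as.integer(seed), out_dir = out_dir,
              band = band, threshold = threshold,
              window_pass1_um = window_pass1_um,
              window_pass2_um = window_pass2_um,
              growth_window_h = growth_window_h,
              growth_min_fraction = growth_min_fraction,
              wave_gap_h = wave_gap_h,
              lumen_diameter_um = lumen_diameter_um,
              n_movies = as.integer(n_movies),
              movie_frames = as.integer(movie_frames))
  stopifnot(cfg$n_embryos >= 1, length(cfg$band) == 2, cfg$band[1] < cfg$band[2],
            cfg$threshold > 0, cfg$window_pass1_um > 0, cfg$window_pass2_um > 0,
            cfg$growth_window_h > 0, cfg$growth_min_fraction >= 0,
            cfg$wave_gap_h > 0, cfg$lumen_diameter_um > 0, cfg$n_movies >= 0)
  structure(cfg, class = "run_config")
}

# Stable fingerprint of a configuration (order-independent of list layout).
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg[sort(names(cfg))]), collapse = "")
  codes <- utf8ToInt(txt)
  sprintf("%08x", sum(codes * (seq_along(codes) %% 97)) %% .Machine$integer.max)
}

#' Run the synthetic study for one genotype
#'
#' Generates a synthetic cohort with the configured preset and runs every
#' analysis stage: compaction angles, cleavage timelines (wave assignment,
#' 8-cell-stage duration, lumen timing, final cell counts), post-lumen
#' growth fits, and optionally short-timescale movies through PIV and the
#' spectral oscillation call. Per-stage tidy CSVs, a summary CSV and a JSON
#' manifest (package version, seed, configuration and its hash) are written
#' to `out_dir`. Deterministic: rerunning with the same configuration
#' yields byte-identical CSVs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the per-stage data frames and the
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  preset <- genotype_preset(config$genotype)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  seed <- config$seed
  out <- list()

  say("stage: compaction angles")
  ang <- make_angle_series(preset, config$n_embryos, seed = seed + 1)
  out$angles <- ang
  utils::write.csv(ang, file.path(config$out_dir, "angles.csv"),
                   row.names = FALSE)

  say("stage: cleavage timelines")
  tls <- make_timeline(preset, config$n_embryos, seed = seed + 2)
  ev <- do.call(rbind, lapply(tls, function(tl) {
    cbind(embryo_id = tl$embryo_id,
          tl$events[c("time_h", "type", "cell_id")])
  }))
  tl_sum <- summarize_timelines(tls)
  out$events <- ev
  out$timelines <- tl_sum
  utils::write.csv(ev, file.path(config$out_dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(tl_sum, file.path(config$out_dir, "timelines.csv"),
                   row.names = FALSE)

  say("stage: post-lumen growth")
  areas <- make_area_series(preset, config$n_embryos, seed = seed + 3)
  fits <- do.call(rbind, lapply(split(areas, areas$embryo_id), function(df) {
    g <- growth_rate(df$time_h, df$area_um2,
                     window_h = config$growth_window_h,
                     min_growth_fraction = config$growth_min_fraction)
    data.frame(embryo_id = df$embryo_id[1],
               rate_um2_min = g$rate_um2_min,
               fractional_increase = g$fractional_increase,
               passes_filter = g$passes_filter)
  }))
  rownames(fits) <- NULL
  out$growth <- fits
  utils::write.csv(fits, file.path(config$out_dir, "growth.csv"),
                   row.names = FALSE)

  calls <- NULL
  if (config$n_movies > 0) {
    say("stage: PIV + oscillation calls (", config$n_movies, " movies)")
    calls <- do.call(rbind, lapply(seq_len(config$n_movies), function(i) {
      oscillating <- with_seed(seed + 100 + i,
                               stats::runif(1) < preset$oscillating_fraction)
      spec <- synthetic_movie_spec(
        n_frames = config$movie_frames,
        oscillation_period = if (oscillating) 80 else 0,
        oscillation_amplitude = if (oscillating) 1.5 else 0,
        seed = seed + 200 + i)
      sm <- make_movie(spec)
      msk <- mask_embryo(sm$movie)
      field <- piv_two_pass(sm$movie,
                            window_pass1_um = config$window_pass1_um,
                            window_pass2_um = config$window_pass2_um,
                            mask = msk)
      ps <- embryo_spectrum(field, embryo_id = sprintf("%s_mov%02d",
                                                       config$genotype, i))
      cl <- call_oscillation(ps, band = config$band,
                             threshold = config$threshold)
      data.frame(embryo_id = cl$embryo_id, amplitude = cl$amplitude,
                 background = cl$background, ratio = cl$ratio,
                 peak_period_s = cl$peak_period,
                 is_oscillating = cl$is_oscillating,
                 truth_oscillating = oscillating)
    }))
    out$oscillation <- calls
    utils::write.csv(calls, file.path(config$out_dir, "oscillation.csv"),
                     row.names = FALSE)
  }

  say("stage: summary")
  pre4 <- ang$angle_deg[ang$stage_tag == "pre4th"]
  summary_df <- rbind(
    cbind(metric = "pre4th_angle_deg", group_summary(pre4)),
    cbind(metric = "stage8_duration_h", group_summary(tl_sum$stage8_duration_h)),
    cbind(metric = "final_cell_count", group_summary(tl_sum$final_cell_count)),
    cbind(metric = "growth_rate_um2_min", group_summary(fits$rate_um2_min)))
  out$summary <- summary_df
  utils::write.csv(summary_df, file.path(config$out_dir, "summary.csv"),
                   row.names = FALSE)

  manifest <- list(package = "blastoquant",
                   version = as.character(utils::packageVersion("blastoquant")),
                   genotype = config$genotype,
                   seed = config$seed,
                   config = unclass(config)[sort(names(unclass(config)))],
                   config_hash = config_hash(unclass(config)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$manifest <- manifest
  invisible(out)
}
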