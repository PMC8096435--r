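#' Genotype presets
#'
#' Parameter sets describing the morphogenesis of each genotype: compaction
#' contact-angle plateaus, 8-cell-stage duration, per-cytokinesis failure
#' probability, post-lumen growth rate, oscillating fraction and the final
#' cell census. Presets ship as a YAML file under `extdata` and drive every
#' synthetic generator. Cohort means are stored with their SEM and cohort
#' size; per-embryo spreads are back-computed as `SEM * sqrt(n)`.
#'
#' @param file path to a preset YAML file. Defaults to the file shipped with
#'   the package.
#' @return `genotype_presets()` returns a named list of presets;
#'   `genotype_preset()` returns a single validated preset (class
#'   `genotype_preset`).
#' @export
genotype_presets <- function(file = system.file("extdata", "genotype_presets.yaml",
                                                package = "blastoquant")) {
  raw <- yaml::read_yaml(file)
  out <- lapply(names(raw), function(nm) {
    p <- raw[[nm]]
    p$name <- nm
    validate_preset(p)
  })
  names(out) <- names(raw)
  out
}

#' @rdname genotype_presets
#' @param name preset name, e.g. `"WT"`, `"mzMyh9"`, `"mzMyh10"`,
#'   `"mzMyh9;mzMyh10"`.
#' @export
genotype_preset <- function(name, file = system.file("extdata", "genotype_presets.yaml",
                                                     package = "blastoquant")) {
  all <- genotype_presets(file)
  if (!name %in% names(all)) {
    stop("unknown genotype preset '", name, "'; available: ",
         paste(names(all), collapse = ", "))
  }
  all[[name]]
}

validate_preset <- function(p) {
  need <- c("name", "angle_start", "angle_end", "stage8_duration",
            "division_failure_prob", "growth_rate", "oscillating_fraction",
            "final_cell_count_mean")
  missing <- setdiff(need, names(p))
  if (length(missing)) stop("preset missing fields: ", paste(missing, collapse = ", "))
  stopifnot(p$angle_start > 0, p$angle_start < 180,
            p$angle_end > 0, p$angle_end < 180,
            p$stage8_duration > 0, p$growth_rate >= 0,
            p$division_failure_prob >= 0, p$division_failure_prob <= 1,
            p$oscillating_fraction >= 0, p$oscillating_fraction <= 1,
            (p$lumen_lead_prob %||% 0) >= 0, (p$lumen_lead_prob %||% 0) <= 1)
  structure(p, class = "genotype_preset")
}

# Between-embryo standard deviations implied by the cohort SEMs.
preset_sds <- function(p) {
  list(
    angle_start = (p$angle_start_sem %||% 0) * sqrt(p$n_angle %||% 1),
    angle_end   = (p$angle_end_sem %||% 0) * sqrt(p$n_angle %||% 1),
    stage8      = (p$stage8_sem %||% 0) * sqrt(p$n_timeline %||% 1),
    growth_rate = (p$growth_rate_sem %||% 0) * sqrt(p$n_growth %||% 1)
  )
}

#' @export
print.genotype_preset <- function(x, ...) {
  cat(sprintf(paste0(
    "<genotype_preset> %s\n",
    "  contact angle: %.0f -> %.0f deg over %.1f h (8-cell stage)\n",
    "  division failure prob: %.3f   growth rate: %.1f um^2/min\n",
    "  oscillating fraction: %.2f    final cell count mean: %.1f\n"),
    x$name, x$angle_start, x$angle_end, x$stage8_duration,
    x$division_failure_prob, x$growth_rate,
    x$oscillating_fraction, x$final_cell_count_mean))
  invisible(x)
}
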