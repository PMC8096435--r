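# blastoquant

Multiscale quantification of mouse preimplantation development from
time-lapse and immunofluorescence imaging.

During the first days of development the mouse embryo compacts, sorts its
first two lineages and inflates a fluid-filled lumen, all powered by
actomyosin contractility. Contractility acts on nested timescales: periodic
cortical contractions with periods of 50–120 s during the 8-cell stage, and
compaction, cleavage and blastocoel growth over tens of hours. blastoquant
implements the full measurement chain used to compare wild-type embryos
with contractility mutants (e.g. maternal-zygotic *Myh9*/*Myh10* knockouts),
for developmental biologists analysing such movies or benchmarking their
own pipelines:

* **PIV** — two-pass cross-correlation particle image velocimetry
  (20 µm → 10 µm interrogation windows, Gaussian subpixel peak,
  normalized-median validation), restricted to the embryo by an
  Otsu-threshold mask (~180 vectors for a 70-µm embryo).
* **Oscillation detection** — per-embryo Fourier power spectra of the
  velocity field; an embryo oscillates when the peak power in the 50–120 s
  band is ≥ 1.7 × the spectrum mean.
* **Morphometrics** — compaction contact angles (three-point annotations),
  post-lumen growth rates (OLS slope over 7 h, µm²/min, 35% growth filter
  for controls), direct least-squares ellipse fits, volume arithmetic.
* **Event logic** — cleavage waves by the 30-min chaining rule, 8-cell-stage
  duration (last third-wave to first fourth-wave division), lumen opening at
  a 20-µm fluid compartment, cell-count bookkeeping including failed and
  reverting cytokineses.
* **Stain quantification** — nuclear/cytoplasmic ratios from 3.7-µm²
  circular ROIs, inner/outer cell classification, apico-basal line
  profiles, reporter intensity, 2^−ΔCT qPCR normalisation.
* **Statistics** — Welch's t, Mann–Whitney U (exact for min(n) ≤ 8),
  Yates-corrected χ², Pearson correlation, group summaries.
* **Synthetic data** — generators for every input above with known ground
  truth and genotype presets (WT, mzMyh9, mzMyh10, mzMyh9;mzMyh10), so the
  entire pipeline runs and validates without microscope data.

## Worked example

Simulate a 10-min short-timescale movie of a pulsating embryo (120 frames,
5 s interval, 80-s contraction period), run PIV inside the embryo mask and
call the oscillation:

```r
library(blastoquant)

sm <- make_movie(synthetic_movie_spec(n_frames = 120, oscillation_period = 80,
                                      oscillation_amplitude = 1.5, seed = 5))
field <- piv_two_pass(sm$movie, mask = mask_embryo(sm$movie))
field
#> <velocity_field> 118 vectors x 119 frame pairs (95.0% valid)
call_oscillation(embryo_spectrum(field, embryo_id = "demo"))
#> <oscillation_call> demo: ratio 27.42 (peak 85 s) -> oscillating
```

The band peak at 85 s is the DFT grid bin adjacent to the true 80-s period,
and a ratio of 27 over background is far above the 1.7 call threshold. The
long-timescale morphometrics of a wild-type cohort at the published size:

```r
wt <- genotype_preset("WT")
ang <- make_angle_series(wt, 23, seed = 1)
group_summary(ang$angle_deg[ang$stage_tag == "pre4th"])
#>    n     mean       sd      sem   median       q1       q3
#> 1 23 145.8188 8.138781 1.697053 145.2124 141.2843 152.6958
tls <- make_timeline(wt, 23, seed = 1)
group_summary(summarize_timelines(tls)$stage8_duration_h)
#>    n     mean       sd       sem median   q1 q3
#> 1 23 7.347826 1.283061 0.2675367    7.5 6.75  8
```

The cohort recovers the preset compaction plateau (147° ± 2 SEM) and
8-cell-stage duration (7.0 h ± 2 SEM). `run_pipeline(run_config("WT"))`
chains all stages and writes tidy per-stage CSVs plus a JSON manifest with
the seed and a configuration hash, so any output traces back to its exact
configuration.

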