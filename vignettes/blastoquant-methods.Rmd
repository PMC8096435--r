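---
title: "Methods: multiscale quantification of preimplantation morphogenesis"
author: "blastoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale quantification of preimplantation morphogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastoquant)
```

## Scope and model

blastoquant quantifies mouse preimplantation development across its nested
timescales. On the short timescale (seconds to minutes), actomyosin
contractility appears as periodic cortical contractions of 8-cell-stage
blastomeres; on the long timescale (hours to days), it drives compaction,
cytokinesis, cell internalisation and blastocoel growth. The package
implements the measurement chain for both scales:

* **PIV** (`piv_two_pass()`): two-pass cross-correlation velocimetry on
  5-s-interval movies — 20 µm interrogation windows on a coarse pass, 10 µm
  windows offset by the rounded coarse prediction on the fine pass, yielding
  on the order of 180 vectors inside a 70-µm embryo.
* **Spectral oscillation call** (`embryo_spectrum()`,
  `call_oscillation()`): per-vector, per-component discrete-Fourier power,
  averaged into one spectrum per embryo; an embryo oscillates when the peak
  power at periods of 50–120 s is at least 1.7× the mean power of its
  spectrum.
* **Morphometrics**: compaction contact angles from three-point
  annotations, projected-area growth rates by OLS over the 7 h after lumen
  opening (µm²/min), direct least-squares ellipse fits for the zona
  pellucida, volume arithmetic.
* **Event logic**: divisions within 30 min of one another form a cleavage
  wave (transitive chaining); the 8-cell-stage duration runs from the last
  third-wave to the first fourth-wave division; lumen opening is the first
  time a ≥ 20 µm fluid compartment is visible; failed cytokineses count as
  wave members without incrementing the cell count.
* **Stain quantification**: nuclear/cytoplasmic ratios from paired
  3.7-µm² circular ROIs, the 5 ICM + 5 polar-TE + 5 mural-TE sampling rule,
  inner/outer classification by medium contact, 15-µm apico-basal line
  profiles min–max normalised to [0, 1], background-corrected reporter
  intensity, and 2^−ΔCT qPCR normalisation.
* **Statistics**: Welch's t, Mann–Whitney U (exact by enumeration for
  min(n) ≤ 8, tie-corrected normal approximation otherwise), Yates-corrected
  χ², Pearson correlation, and the group summaries used in reporting
  (significance is conventionally read at p < 10⁻²).

No microscope data ship with the package; a synthetic generator produces
every input with known ground truth, so the full chain is testable end to
end.

## The synthetic generator and its presets

`genotype_presets()` encodes, per genotype, the measured morphogenesis
parameters: compaction plateaus (e.g. wild type 87° → 147°; the
*Myh9* maternal-zygotic mutant 85° → 125°; the double mutant capping at
117°), 8-cell-stage durations (7.0 h wild type, 9.8 h single mutant),
post-lumen growth rates (≈ 4 µm²/min across genotypes), oscillating
fractions, and division-failure probabilities.

Design choices that were genuinely open:

* **Angle ramp shape.** Compaction trajectories are sigmoidal but no
  functional form is canonical; we use a logistic ramp rescaled to hit the
  start and plateau angles exactly at the stage boundaries. Sampling points
  mirror the four scoring stages (post-3rd, pre-4th, post-4th, pre-5th
  cleavage).
* **Variance decomposition.** Published cohort values are mean ± SEM at a
  given n, so the per-embryo spread is back-computed as SEM·√n. We model
  that spread as *between-embryo* variation of the plateau parameters and
  add a small (2°) i.i.d. measurement noise at each sampling point. A pure
  measurement-noise model would bias any per-embryo "maximal angle"
  statistic upward (a maximum over several noisy samples), whereas plateau
  variation between embryos reproduces both the cohort SEM and an unbiased
  plateau readout.
* **Division-failure probability.** The five-wave cleavage model starts
  from one cell; every cell attempts cytokinesis in each wave and fails
  independently with probability *p*, so the expected final count is
  (2 − p)⁵. The double-mutant preset back-computes *p* from the observed
  mean census of 2.9 cells: p = 2 − 2.9^(1/5) ≈ 0.763. The single-mutant
  preset scales the blastocyst census ratio into the five-wave model the
  same way (p ≈ 0.31). Failed attempts are recorded as events, so wave
  assignment and stage durations remain measurable even for single-celled
  embryos.
* **Intra-wave jitter** is uniform on [0, 25) min and event times are
  snapped to the 30-min acquisition grid, so the 30-min chaining rule
  recovers the simulated waves by construction.
* **Inter-wave gaps** other than the 8-cell stage are not individually
  published; 10 h is used as a realistic cleavage-cycle default. The lumen
  opens 1.5 h after the fifth wave, except with the preset's lead
  probability (e.g. 5/11 for the *Myh9* mutant) it precedes the fifth wave
  by 1 h.
* **Movies.** The synthetic embryo is a speckle-textured disk whose radius
  follows R + A·sin(2πt/T); the texture is band-pass Gaussian noise with a
  1-µm correlation length, advected by the uniform dilation so PIV has
  trackable, boundary-consistent signal. The speckle grain matters: the
  10-µm fine interrogation window must contain tens of independent
  speckles for the correlation peak to dominate its neighbours.

What the generator does *not* emulate: out-of-focus light, photobleaching,
non-radial cortical flows, cell-scale heterogeneity of the contraction
phase, or 3D geometry. Passing recovery tests therefore demonstrates the
correctness of the measurement chain, not robustness to every optical
artefact of real microscopy.

## Numerical choices

* PIV correlation is computed in the frequency domain after window-mean
  subtraction, zero-padded (linear, not circular) and normalized by the
  overlap area; the search is limited to a quarter of the window per pass
  (plus whatever a frame-edge clamp takes away), and the coarse predictor
  field is median-filtered (3×3) before use. Subpixel localisation uses the
  three-point Gaussian estimator with a parabolic fallback where a
  logarithm would be undefined. Outliers are flagged by the normalized
  median test (threshold 2, 8-neighbourhood) and replaced by the local
  median.
* Spectra use no taper (records are ~120 samples and the band statistic is
  a maximum); the DC bin is excluded everywhere; the background mean
  includes the 50–120 s band; the 1.7× comparison is inclusive at exactly
  1.7. Per-series mean removal makes calls invariant to constant drift.
* The Mann–Whitney exact/approximate switch sits at min(n) = 8; the
  enumeration handles midrank ties, which the classical exact tables do
  not.
* Degenerate inputs are explicit: zero-variance PIV windows are flagged
  invalid rather than divided by; a constant line profile cannot be
  min–max normalised and returns zeros with a `degenerate` attribute;
  blank movies give an empty mask and a "no embryo" error downstream;
  plateau ties in `max_compaction()` break to the earliest time.
* `growth_rate()` defaults to the OLS slope over the 7-h window (an
  endpoint-difference estimator is available); the 35% minimal-growth
  filter applies to control embryos only.

## Problem sizes

The test-suite and acceptance computations run at the published cohort
sizes (23 wild-type, 15 single-mutant, 8 and 3 double-mutant embryos), with
synthetic movies of 128×128 px at 0.7 µm/px and 120 frames at 5 s — the
10-min short-timescale record. The white-noise null for the oscillation
call uses 200 seeded velocity fields; wave-rule equivalence is checked
against brute-force chaining on 1000 random timelines.

## Known limitations

* Recovery targets at n = 3 and n = 8 inherit the large sampling variance
  of those cohort sizes; individual seeds can land near the edge of the
  ±2 SEM acceptance band. That spread is a property of the study design,
  not of the estimators.
* The PIV implementation does not deform windows; strongly sheared flows
  would be underestimated. Cortical pulsation of an 8-cell embryo is well
  within its regime.
* Inner/outer classification operates on 2D equatorial label masks; cells
  touching the medium only above or below the plane would be
  misclassified in real 3D data.
* The five-wave timeline model stops at lumen opening; published
  blastocyst cell counts that include later divisions are carried in the
  presets as metadata, not reproduced by the generator.
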