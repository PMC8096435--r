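# Genotype presets for the synthetic-data generators.
#
# Angles are cohort means +/- SEM (degrees) at the cohort size n_angle;
# stage8_duration is the 8-cell-stage duration (h, last third-wave division
# to first fourth-wave division); growth_rate is the projected-area inflation
# rate after lumen opening (um^2/min); oscillating_fraction is the proportion
# of embryos whose velocity power spectrum passes the 1.7x band criterion;
# division_failure_prob is the per-cytokinesis failure probability of the
# five-wave cleavage model; lumen_lead_prob is the probability that lumen
# opening precedes the fifth cleavage wave. Between-embryo spreads are
# back-computed in code as SEM * sqrt(n).
WT:
  angle_start: 87
  angle_start_sem: 3
  angle_end: 147
  angle_end_sem: 2
  n_angle: 23
  stage8_duration: 7.0
  stage8_sem: 0.3
  n_timeline: 23
  division_failure_prob: 0.0
  growth_rate: 3.9
  growth_rate_sem: 0.5
  n_growth: 20
  oscillating_fraction: 0.857
  final_cell_count_mean: 58.1
  lumen_lead_prob: 0.0
mzMyh9:
  angle_start: 85
  angle_start_sem: 2
  angle_end: 125
  angle_end_sem: 4
  n_angle: 15
  stage8_duration: 9.8
  stage8_sem: 0.5
  n_timeline: 15
  division_failure_prob: 0.307
  growth_rate: 3.9
  growth_rate_sem: 1.0
  n_growth: 9
  oscillating_fraction: 0.067
  final_cell_count_mean: 25.2
  lumen_lead_prob: 0.455
mzMyh10:
  angle_start: 87
  angle_start_sem: 5
  angle_end: 121
  angle_end_sem: 4
  n_angle: 11
  stage8_duration: 7.0
  stage8_sem: 0.4
  n_timeline: 11
  division_failure_prob: 0.0
  growth_rate: 4.0
  growth_rate_sem: 0.5
  n_growth: 7
  oscillating_fraction: 0.273
  final_cell_count_mean: 55.0
  lumen_lead_prob: 0.0
mzMyh9;mzMyh10:
  angle_start: 85
  angle_start_sem: 3
  angle_end: 117
  angle_end_sem: 4
  n_angle: 3
  stage8_duration: 12.0
  stage8_sem: 0.7
  n_timeline: 8
  division_failure_prob: 0.762682
  growth_rate: 5.8
  growth_rate_sem: 1.5
  n_growth: 5
  oscillating_fraction: 0.0
  final_cell_count_mean: 2.9
  lumen_lead_prob: 0.0
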