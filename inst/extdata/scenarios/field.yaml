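# Field trial: 9 RILs x 3 replicate fields, split-plot N main effect
# (155 kg N/ha urea vs none). Low N shrinks RHL by 30 %, shoot biomass at
# flowering by 45 % and yield by 12 %. Field scatter is dominated by
# RIL-level deviations unrelated to RHL (ril_scatter_frac, slope-neutral
# by construction, calibrated so the mean low-N regression R-squared of
# the default scenario falls in 0.2-0.35) on top of plot-level
# measurement noise. Absolute scales and noise values invented.
name: field
design: splitplot
n_form: mixed
treatments: [HN, LN]
n_rate_kg_ha: {HN: 155, LN: 0}
reps: 3
rils:
  names: [RIL01, RIL02, RIL03, RIL04, RIL05, RIL06, RIL07, RIL08, RIL09]
  rhl_baseline_mm: [0.20, 0.30, 0.40, 0.50, 0.60, 0.70, 0.80, 0.90, 1.00]
rhl_treatment_multiplier: {HN: 1.0, LN: 0.70}   # low N: -30 % RHL
rhl_noise_cv: 0.10
trait_noise_cv: 0.10
ril_scatter_frac: 1.0
rep_sd_frac: 0.03
wholeplot_sd_frac: 0.03
traits:
  leaf_area_cm2:
    baseline: 4500.0
    treatment_multiplier: {HN: 1.0, LN: 0.70}
    endpoint_ratio: {HN: 1.0, LN: 2.50}
  shoot_g:
    baseline: 150.0
    treatment_multiplier: {HN: 1.0, LN: 0.55}   # -45 % at flowering
    endpoint_ratio: {HN: 1.0, LN: 3.50}         # +250 % across the RHL range
  yield_g:
    baseline: 130.0
    treatment_multiplier: {HN: 1.0, LN: 0.88}   # -12 % yield
    endpoint_ratio: {HN: 1.0, LN: 3.67}         # +267 % across the RHL range
  n_mg:
    baseline: 1800.0
    treatment_multiplier: {HN: 1.0, LN: 0.55}
    endpoint_ratio: {HN: 1.0, LN: 3.00}         # +200 % across the RHL range
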