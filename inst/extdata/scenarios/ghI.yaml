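# Greenhouse trial I: ammonium as the sole N source, 6 RILs x 4 blocks,
# RCBD, high N 7000 uM vs low N 700 uM. Effects are encoded as ratios and
# multipliers; absolute trait scales and all noise parameters are invented
# (the underlying trials report effects, not raw data).
name: ghI
design: rcbd
n_form: ammonium
treatments: [HN, LN]
n_supply_um: {HN: 7000, LN: 700}
blocks: 4
rils:
  names: [RIL01, RIL02, RIL03, RIL04, RIL05, RIL06]
  # baseline RHL (mm), spread evenly over the natural 0.2-1.0 mm range
  rhl_baseline_mm: [0.20, 0.36, 0.52, 0.68, 0.84, 1.00]
rhl_treatment_multiplier: {HN: 1.0, LN: 1.0}   # ammonium stress: no RHL response
rhl_noise_cv: 0.10
trait_noise_cv: 0.10
block_sd_frac: 0.03
traits:
  shoot_g:
    baseline: 12.0
    treatment_multiplier: {HN: 1.0, LN: 0.77}   # low ammonium: -23 % shoot
    endpoint_ratio: {HN: 1.0, LN: 1.44}         # +44 % across the RHL range
  n_mg:
    baseline: 300.0
    treatment_multiplier: {HN: 1.0, LN: 0.62}   # invented scale of N stress
    endpoint_ratio: {HN: 1.0, LN: 1.71}         # +71 % across the RHL range
  root_g:
    baseline: 2.5
    treatment_multiplier: {HN: 1.0, LN: 0.87}   # root:shoot up 13 % under LN
    endpoint_ratio: {HN: 1.0, LN: 1.0}
  root_length_cm:
    baseline: 5000.0
    treatment_multiplier: {HN: 1.0, LN: 1.0}    # total root length unaffected
    endpoint_ratio: {HN: 1.0, LN: 1.0}
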