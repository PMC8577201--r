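# Default maize seedling root-system parameterization (plausible seedling
# values; the sweeps contrast hair phenes only, everything else held fixed).
# Units: cm, days, degrees; hair lengths in mm.
elongation_rate_cm_d:
  primary: 2.0
  seminal: 1.5
  lateral: 0.5
seminal_count: 3
branching_interval_cm: 0.8
lateral_delay_d: 1.0
insertion_angle_deg:
  primary: 0
  seminal: 40
  lateral: 70
gravitropism_deg_per_cm:
  primary: 0
  seminal: 3
  lateral: 0
radius_cm:
  primary: 0.025
  seminal: 0.020
  lateral: 0.010
max_root_hair_length_mm: 0.5
root_hair_growth_rate_mm_d: 0.25
hair_free_tip_zone_cm: 0.5
root_hair_density_per_cm: 500
hair_radius_cm: 0.0005
dt_max_d: 0.25
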