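# Soil mineral N depth profiles at 63 days after planting: four sampled
# layers, ammonium and nitrate, high-N vs low-N split plots. The top-layer
# ammonium share of total available N is the treatment signature (11 % in
# high-N, 21 % in low-N soil); absolute concentrations and the depth decay
# are invented with literature-typical magnitudes.
name: soil
treatments: [HN, LN]
depth_layers_cm: ["0-15", "15-30", "30-45", "45-60"]
species: [NH4, NO3]
top_layer_total_mg_kg: {HN: 30.0, LN: 12.0}   # total mineral N, topsoil
top_layer_nh4_fraction: {HN: 0.11, LN: 0.21}
depth_decay: 0.55                              # per-layer multiplier
noise_cv: 0.0
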