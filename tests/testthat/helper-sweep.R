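# The reduced factorial sweep (3 hair lengths x 2 densities x 2 N rates x
# 2 transpiration fractions on the default 5 mm grid) takes a couple of
# minutes, so it is computed once per test run and shared by the
# simulator-property and uptake-pattern tests. A common scenario seed
# keeps the axis geometry identical across hair-phene levels, isolating
# the hair effect.
.sweep_fixture <- new.env(parent = emptyenv())

reduced_sweep <- function() {
  if (is.null(.sweep_fixture$tbl)) {
    .sweep_fixture$tbl <- run_sweep(
      rhl_levels = c(0, 0.5, 1),
      rhd_levels = c(100, 1000),
      n_levels = c(62.4, 145.6),
      transpiration_levels = c(0.25, 1),
      base = scenario_config(seed = 101L),
      common_seed = TRUE)
  }
  .sweep_fixture$tbl
}
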