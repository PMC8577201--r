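---
title: "Methods: simulating root-hair-mediated nitrogen acquisition and analysing RIL trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating root-hair-mediated nitrogen acquisition and analysing RIL trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and intent

`rhizoN` is a heuristic, desk-scale functional-structural model of nitrogen
capture by a maize seedling root system, together with generators for
synthetic greenhouse and field recombinant-inbred-line (RIL) trials and the
statistical chain used to analyse them. The simulator is built to expose
*mechanistic orderings* — how root hair length (RHL), root hair density
(RHD), soil N supply and transpiration-driven mass flow interact — not to
predict absolute uptake of any particular cultivar. The statistics side is
built for *parameter recovery*: every effect a scenario file encodes can be
re-estimated from the generated data by the same analyses an agronomist
would run (blocked ANOVA, protected LSD, per-treatment regression,
endpoint percent change).

## The root system

The architecture is deliberately minimal: one vertical primary axis, a
whorl of `seminal_count` (default 3) seminal axes inserted at 40 degrees
from vertical, and first-order laterals emitted behind primary/seminal
tips every `branching_interval_cm` (0.8 cm) that emerge after
`lateral_delay_d` (1 d). Tips elongate at class-specific rates (2.0 / 1.5 /
0.5 cm d^-1) and bend toward the vertical at a class gravitropism rate;
lateral azimuths are jittered deterministically from the scenario seed, so
a given seed always yields a byte-identical segment table and the
architecture is identical across hair-phene levels (hairs never touch axis
geometry). These rates are plausible seedling values chosen once and
shipped in `inst/extdata/maize_seedling.yaml`; the published experiments
this package mirrors contrast hair phenes with "everything else held
constant", so the contrasts — not the absolute architecture — carry the
conclusions.

Root hairs are statistical properties of a segment, never individual
geometric objects: a segment carries a hair density (hairs cm^-1 of axis,
taken literally per cm of axis length, the unit in which hair densities
are reported), a hair radius (5 um), and a current hair length that ramps
from zero behind a hair-free tip zone (0.5 cm) at the hair growth rate
until it saturates at the phenotype's maximum `l_max`. Different RHL
phenotypes are produced by varying the hair growth rate (`l_max / 2` per
day), so hairs reach full length in two days, and absorptive area follows
`2 pi r L` for the axes plus `density x length x 2 pi r_hair x l_hair` for
the hairs.

Time steps are fixed at `dt = 0.25 d`; hairs ride the same clock. Growth
calls subdivide internally, so advancing 15 days in one call or in sixty
is identical. Coordinates are cm, origin at the seed, z positive downward;
hair lengths alone are mm, mirroring field usage.

## Soil nitrogen

Soil is a closed box of cubic voxels (default 20 x 20 x 40 cm at 5 mm
resolution, 128,000 voxels). Each species (nitrate, ammonium) has a
solution concentration per cm^3 of soil, a constant buffer capacity `b`
(total-to-dissolved ratio; nitrate 2, ammonium 10) and an effective
diffusivity `D_e` (nitrate 0.05, ammonium 0.005 cm^2 d^-1). These defaults
are assumptions with literature-typical magnitudes — the species contrast
(ammonium strongly sorbed and slow, nitrate mobile) matters more than the
absolute numbers, because it is what makes ammonium uptake
diffusion-limited. Buffered diffusion `b dC/dt = D_e lap(C)` is advanced
by an explicit 6-neighbour scheme in flux form, which conserves mass to
rounding; steps beyond the stability bound `b h^2 / (6 D_e)` raise an
error and the engine subcycles instead. All faces are zero-flux: a closed
pot, which makes conservation exactly auditable — every simulation
carries a ledger whose residual (initial N minus soil N minus plant N) is
checked at 1e-8 relative.

Field-style N supply (kg N ha^-1) converts exactly to an areal density
(1 kg ha^-1 = 0.01 mg cm^-2) distributed uniformly over the column by
default (an exponential profile is available; how the reference
experiments distributed N with depth is not stated). Mineralization and
leaching are off by default so the N budget is fixed.

## Uptake

Each step, segments are mapped to the voxels within `radius + hair
length` of the axis by midpoint sampling at 1 mm spacing; weights sum to
the segment length. Active uptake follows Michaelis-Menten kinetics — the
standard choice in nutrient-uptake models; no particular kinetic law is
prescribed by the experiments themselves — on the reach-weighted mean
concentration, applied to the full absorptive area (hairs included) with
one `(I_max, K_m)` pair (defaults 2 umol cm^-2 d^-1 and 0.05 umol cm^-3)
for root and hair surface alike.

Because hairs operate below the 5 mm voxel resolution, the demand is
capped by the N accessible within the segment's *depletion shell*: the
cylinder of radius `r + l_hair + sqrt(4 D_e dt / b)` (hair reach plus one
step of diffusive resupply). This `min(demand, shell N)` cap is what
preserves the hair-length signal on a coarse grid — longer hairs reach a
larger shell — and is exact in the ample-N regime, which keeps the
uptake arithmetic hand-checkable. Mass flow is not a water PDE: the
transpiration stream `f_T x W x shoot biomass` (W = 100 cm^3 water per g
shoot per day, interpreted per day; the fraction `f_T` is the mass-flow
dial) is apportioned over segments by absorptive area and delivers
`water x local concentration` convectively. At `f_T = 0` the mass-flow
ledger is identically zero. When several segments draw on one voxel the
withdrawals are rationed proportionally to demand — hair-hair and
root-root competition emerge from this shared cap rather than from any
explicit competition term.

Shoot biomass is the minimum of a logistic potential trajectory (B0 =
0.05 g, r = 0.35 d^-1, K = 5 g) and an N-limited trajectory `B0 + plant N
/ nu` with `nu = 1500 umol N per g` (about 2.1 % N by mass) and a seed
reserve of 400 umol. This deliberately collapses a full carbon/water
budget into one scalar coupling: uptake, not growth realism, is what the
factorial sweeps read out. Cumulative uptake is interpreted as the
15-day total (the sweep's headline output), split exactly into diffusive
and mass-flow ledgers.

## What the sweep shows

The reference factorial is 7 RHL x 3 RHD x 3 N x 4 transpiration = 252
scenarios of 15 simulated days; the test suite exercises a reduced 3 x 2
x 2 x 2 sweep on the default grid (24 scenarios, a few minutes on one
CPU) — sizes chosen as a matter of proportion for a desk-scale package.
On that sweep the package asserts orderings, not magnitudes: uptake is
non-decreasing in RHL and RHD everywhere; the *relative* benefit of long
hairs under low N and high density is largest when transpiration is cut
to 25 %, i.e. hairs matter most where mass flow is weakest and uptake is
diffusion-limited; and root-adjacent voxels end below the bulk mean
concentration under pure diffusion (a depletion zone). Published
R-squared values for uptake-RHL regressions from other simulators are
*not* reproduction targets — different internals, different variances —
only the sign and ordering structure is.

## The trial generators

The generators exist so the statistics stage can be tested by parameter
recovery without any external data. Scenario YAMLs encode *effects* as
ratios and multipliers: the RHL response to N stress (x1.21 under low
nitrate, x1.00 under low ammonium, x0.70 in the low-N field), per-trait
treatment multipliers (e.g. low-N field shoot x0.55, yield x0.88), and
per-trait *endpoint ratios* — the predicted trait at the longest hairs
over the shortest within a treatment (e.g. 3.16 for greenhouse-II
biomass, 3.67 for field yield). Absolute trait scales (12 g greenhouse
shoots, 130 g yields, ...) and all noise parameters are invented and
flagged as such in the files. Baseline RHL for the 6 or 9 RILs is spread
evenly over 0.2-1.0 mm, the natural range, maximizing regression
leverage.

Generation is: RHL = baseline x treatment multiplier x mean-one lognormal
noise; then per trait and treatment a line in RHL is solved so that the
predicted endpoint ratio over the *realized* RHL range equals the
configured ratio, anchored at the treatment mean, and values are the line
times lognormal noise plus additive block (or rep and whole-plot) effects.
Zero noise therefore recovers every configured effect exactly — the
round-trip is an identity, tested at 1e-6 — and noisy recovery is
unbiased to within a small ratio-estimator term measured in the tests.

Field scatter needed a design decision. Regressions of field traits on
RHL are reported with R-squared near 0.2-0.3, which is far more scatter
than plot-level measurement noise alone can represent while keeping a
3.5-fold endpoint ratio stably estimable from 27 plots: with all scatter
at plot level the endpoint percent-change estimator becomes unstable and
upward-biased. The field scenario therefore splits scatter into
plot-level lognormal noise (CV 0.10, like the greenhouse) plus RIL-level
deviations expanded to plots and *residualized against (1, RHL) within
each treatment* — exactly slope-neutral by construction, rescaled per
seed when needed to keep traits positive. The deviation scale
(`ril_scatter_frac = 1.0`) was calibrated once by Monte-Carlo so the mean
low-N regression R-squared of the default scenario lands inside 0.2-0.35,
and then frozen. The cost of this choice is explicit: the generated
genotype deviations carry no information about RHL by construction, so
the generator cannot emulate confounded genotype effects; it emulates a
world where the configured RHL-trait line is the truth and everything
else is noise. Passing recovery tests therefore show the analysis chain
is correct and stable, not that real field data are this well behaved.

The soil-profile generator is simpler: four sampled depth layers by two
species by two treatments, a configured topsoil ammonium share of total
mineral N per treatment (0.11 high-N, 0.21 low-N), geometric decay with
depth (x0.55 per layer, both species, so the share is depth-constant),
zero noise by default.

## The analysis chain

- `fit_linear` / `fit_quadratic`: ordinary least squares with R-squared,
  slope standard error and two-sided tests (model F for the quadratic).
  An exactly constant response is reported as slope 0 with R-squared 0.
- `percent_change_from_fit`: `100 (yhat(x_max) - yhat(x_min)) /
  yhat(x_min)`; endpoints default to the observed range of the analysed
  subset, and the generators store their realized per-treatment RHL
  endpoints so recovery evaluates the fit where the line was anchored. A
  nonpositive baseline prediction is an error, never a silent NA.
- `two_way_block_anova`: balanced complete designs only (the generators
  guarantee balance; unbalanced input errors out rather than silently
  switching SS types). Block is a fixed additive factor: in balanced
  designs the genotype/treatment/interaction F-tests coincide with the
  random-block mixed-model tests, which removes the mixed-model machinery
  without changing the reported inferences. The split-split-plot third
  factor of the original field design is collapsed to split-plot, matching
  the analyses actually performed on such data.
- `protected_lsd`: Fisher's LSD at D = 0.05 only after a significant
  omnibus F (no letters otherwise). Letters come from a descending
  insert-and-absorb sweep; a difference exactly equal to the LSD counts
  as non-significant. Two levels share a letter if and only if their
  means differ by at most the LSD — tested against exhaustive pairwise
  comparison. No multiple-testing correction beyond protection is
  applied, matching common practice for these trials.
- `treatment_percent_difference`: percent difference of raw treatment
  means.

Under a complete-null generator the protected LSD separates any pair in
at most alpha of datasets plus Monte-Carlo margin (500-seed test).

## Numerical choices, degenerate inputs, determinism

Diffusion refuses unstable steps (the engine subcycles); withdrawal never
drives a concentration negative; an empty root system or zero
concentration yields exactly zero uptake; `duration = 0` echoes the
initial state; zero N supply pins biomass to the seed-reserve floor. All
randomness — architecture azimuths, generator noise — derives from
explicit seeds; azimuths use a counter-based hash rather than the global
RNG stream so growth is reproducible regardless of how calls are
partitioned. Sweep cells get independent seeds derived from the master
seed (or a common seed when isolating hair effects).

## Known limitations

No second-order laterals, crown/brace flushes, root mortality, exudation
or mechanical impedance; no water PDE (mass flow is a demand dial, so
soil drying feedbacks are absent); one kinetic constant pair for all
surfaces; the sub-voxel depletion shell is a first-order stand-in for
true rhizosphere gradients; the trial generators encode effects as
ratios, so they can only show that configured effects are recoverable,
not that the underlying field biology is linear in RHL.
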