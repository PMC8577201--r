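#' Load a packaged (or user) trial scenario
#'
#' Scenario files encode trial structure (RILs, blocks/reps, treatments)
#' and the generative effect sizes: the RHL response to N stress as a
#' treatment multiplier, per-trait treatment multipliers, and per-trait
#' endpoint ratios (predicted trait at maximum RHL over minimum RHL within
#' a treatment). Packaged scenarios: `"ghI"`, `"ghII"`, `"field"`,
#' `"soil"`.
#'
#' @param name Scenario name (packaged) or a path to a YAML file.
#' @return A `trial_scenario` list.
#' @export
load_trial_scenario <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "scenarios", paste0(name, ".yaml"),
                package = "rhizoN")
  if (!nzchar(path) || !file.exists(path)) {
    stop(sprintf("No scenario '%s' (not a packaged name, not a file).", name),
         call. = FALSE)
  }
  sc <- yaml::read_yaml(path)
  structure(sc, class = "trial_scenario")
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat(sprintf("<trial_scenario> %s (%s)\n", x$name,
              x$design %||% "soil profile"))
  invisible(x)
}

# mean-one multiplicative lognormal factors
lnorm_factor <- function(n, cv) {
  z <- stats::rnorm(n)
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(z * sigma - sigma^2 / 2)
}

# Solve the trait regression line y = a + b x within one treatment so that
# yhat(x_max)/yhat(x_min) equals the endpoint ratio R over the realized RHL
# values x, anchored so that mean(yhat(x)) equals the treatment mean M.
solve_trait_line <- function(x, R, M) {
  if (R == 1) return(c(a = M, b = 0))
  x_min <- min(x); x_max <- max(x)
  denom <- x_max - R * x_min
  if (denom <= 0) {
    stop(sprintf(
      "Endpoint ratio %g is infeasible for the RHL range [%g, %g]: implied intercept is nonpositive.",
      R, x_min, x_max), call. = FALSE)
  }
  a <- M / (1 + (R - 1) * mean(x) / denom)
  b <- a * (R - 1) / denom
  if (a + b * x_min <= 0) {
    stop("Infeasible regression anchor: nonpositive trait at minimum RHL.",
         call. = FALSE)
  }
  c(a = a, b = b)
}

trait_cv <- function(scenario, trait) {
  tr <- scenario$traits[[trait]]
  if (!is.null(tr$noise_cv)) tr$noise_cv else scenario$trait_noise_cv
}

# Shared generative core for greenhouse (RCBD, `blocks`) and field
# (split-plot, `reps`) trials.
generate_trial <- function(scenario, seed, unit_col, n_units,
                           wholeplot = FALSE) {
  set.seed(seed)
  rils <- scenario$rils$names
  base_rhl <- unlist(scenario$rils$rhl_baseline_mm)
  stopifnot(length(base_rhl) == length(rils), all(base_rhl > 0))
  treatments <- unlist(scenario$treatments)
  m_rhl <- unlist(scenario$rhl_treatment_multiplier)
  stopifnot(all(m_rhl > 0))

  design <- expand.grid(ril = rils, unit = seq_len(n_units),
                        treatment = treatments,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ril_idx <- match(design$ril, rils)
  rhl <- unname(base_rhl[ril_idx] * m_rhl[design$treatment] *
                  lnorm_factor(nrow(design), scenario$rhl_noise_cv))

  endpoints <- lapply(treatments, function(tr) {
    xs <- rhl[design$treatment == tr]
    c(x_min = min(xs), x_max = max(xs))
  })
  names(endpoints) <- treatments

  unit_sd_frac <- if (wholeplot) scenario$rep_sd_frac else
    scenario$block_sd_frac
  out <- tibble::tibble(ril = design$ril, unit = design$unit,
                        treatment = design$treatment, rhl_mm = rhl)
  names(out)[names(out) == "unit"] <- unit_col

  lines <- list()
  for (trait in names(scenario$traits)) {
    tr <- scenario$traits[[trait]]
    mult <- unlist(tr$treatment_multiplier)
    ratio <- unlist(tr$endpoint_ratio)
    stopifnot(all(mult > 0), all(ratio > 0))
    cv <- trait_cv(scenario, trait)
    unit_eff <- stats::rnorm(n_units, 0, unit_sd_frac * tr$baseline)
    wp_eff <- if (wholeplot) {
      matrix(stats::rnorm(n_units * length(treatments), 0,
                          scenario$wholeplot_sd_frac * tr$baseline),
             nrow = n_units, dimnames = list(NULL, treatments))
    }
    mu <- numeric(nrow(design))
    for (trt in treatments) {
      sel <- design$treatment == trt
      ab <- solve_trait_line(rhl[sel], ratio[[trt]],
                             tr$baseline * mult[[trt]])
      mu[sel] <- ab["a"] + ab["b"] * rhl[sel]
      lines[[paste(trait, trt, sep = ".")]] <-
        c(a = unname(ab["a"]), b = unname(ab["b"]))
    }
    # Slope-neutral RIL-level scatter: per-RIL deviations expanded to
    # plots and residualized against (1, RHL) within each treatment, so
    # they widen the regression scatter (lowering R^2 to field-like
    # levels) without perturbing the recoverable trait-RHL line. The
    # scatter vector is rescaled (which keeps it exactly slope-neutral)
    # when needed to keep every trait value positive.
    scatter_frac <- tr$ril_scatter_frac %||% scenario$ril_scatter_frac %||% 0
    scatter <- numeric(nrow(design))
    if (scatter_frac > 0) {
      gdev <- matrix(pmin(4, pmax(0.25, lnorm_factor(
        length(rils) * length(treatments), scatter_frac))),
        nrow = length(rils), dimnames = list(rils, treatments))
      raw <- mu * (gdev[cbind(ril_idx, match(design$treatment, treatments))] - 1)
      for (trt in treatments) {
        sel <- design$treatment == trt
        scatter[sel] <- stats::lm.fit(cbind(1, rhl[sel]), raw[sel])$residuals
      }
    }
    value <- mu * lnorm_factor(nrow(design), cv) + unit_eff[design$unit]
    if (wholeplot) {
      value <- value + wp_eff[cbind(design$unit,
                                    match(design$treatment, treatments))]
    }
    if (any(scatter != 0)) {
      floor_v <- 0.02 * mu
      neg <- scatter < 0 & (value + scatter) < floor_v
      lambda <- if (any(neg)) {
        min(1, min((value[neg] - floor_v[neg]) / -scatter[neg]))
      } else 1
      value <- value + max(0, lambda) * scatter
    }
    if (any(value <= 0)) {
      stop(sprintf(
        "Generated nonpositive '%s'; reduce the noise CV or block SD.",
        trait), call. = FALSE)
    }
    out[[trait]] <- value
  }
  attr(out, "scenario") <- scenario
  attr(out, "seed") <- seed
  attr(out, "rhl_endpoints") <- endpoints
  attr(out, "trait_lines") <- lines
  class(out) <- c("trial_table", class(out))
  out
}

#' Generate a synthetic greenhouse trial
#'
#' Emulates a 6-RIL randomized complete block greenhouse trial (4 blocks,
#' high vs low N). Per plot: RHL is the RIL baseline times the N-stress
#' multiplier times mean-one lognormal noise; each trait follows a line in
#' RHL solved so that the predicted endpoint ratio over the realized RHL
#' range equals the scenario's configured ratio, anchored at the treatment
#' mean, then multiplied by lognormal noise and shifted by an additive
#' block effect. Fully reproducible from the seed.
#'
#' @param scenario A `trial_scenario` (e.g. `load_trial_scenario("ghII")`)
#'   or a scenario name.
#' @param seed Integer seed.
#' @return A `trial_table` tibble, one row per plot, with columns `ril`,
#'   `block`, `treatment`, `rhl_mm` and one column per trait. Attributes:
#'   `rhl_endpoints` (realized per-treatment RHL range used to anchor the
#'   lines), `trait_lines` (the generative intercept/slope), `scenario`,
#'   `seed`.
#' @examples
#' tab <- gen_greenhouse("ghII", seed = 1)
#' head(tab)
#' @export
gen_greenhouse <- function(scenario, seed = 1L) {
  if (is.character(scenario)) scenario <- load_trial_scenario(scenario)
  stopifnot(inherits(scenario, "trial_scenario"),
            identical(scenario$design, "rcbd"))
  generate_trial(scenario, seed, unit_col = "block",
                 n_units = scenario$blocks, wholeplot = FALSE)
}

#' Generate a synthetic field trial
#'
#' Emulates a 9-RIL split-plot field trial (3 replicate fields; N level as
#' the main-plot factor). Structure as [gen_greenhouse()] with an additive
#' replicate effect plus a whole-plot (rep x N level) error term, and the
#' field trait set (leaf area, shoot biomass at flowering, yield, plant N).
#'
#' @inheritParams gen_greenhouse
#' @return A `trial_table` with columns `ril`, `rep`, `treatment`,
#'   `rhl_mm`, `leaf_area_cm2`, `shoot_g`, `yield_g`, `n_mg`.
#' @export
gen_field <- function(scenario = "field", seed = 1L) {
  if (is.character(scenario)) scenario <- load_trial_scenario(scenario)
  stopifnot(inherits(scenario, "trial_scenario"),
            identical(scenario$design, "splitplot"))
  generate_trial(scenario, seed, unit_col = "rep",
                 n_units = scenario$reps, wholeplot = TRUE)
}

#' Generate a synthetic soil mineral-N depth profile
#'
#' Four sampled layers by two species (ammonium, nitrate) by two N
#' treatments. The top-layer ammonium fraction of total mineral N is set
#' per treatment; concentrations decay geometrically with depth; optional
#' mean-one lognormal noise (default none).
#'
#' @inheritParams gen_greenhouse
#' @return A `trial_table` with columns `treatment`, `depth_layer`
#'   (ordered factor), `species` (`NH4`/`NO3`) and `concentration`
#'   (mg N per kg soil).
#' @export
gen_soil_profile <- function(scenario = "soil", seed = 1L) {
  if (is.character(scenario)) scenario <- load_trial_scenario(scenario)
  stopifnot(inherits(scenario, "trial_scenario"))
  set.seed(seed)
  treatments <- unlist(scenario$treatments)
  layers <- unlist(scenario$depth_layers_cm)
  fracs <- unlist(scenario$top_layer_nh4_fraction)
  if (any(fracs <= 0 | fracs >= 1)) {
    stop("Top-layer ammonium fractions must lie strictly in (0, 1).",
         call. = FALSE)
  }
  totals <- unlist(scenario$top_layer_total_mg_kg)
  decay <- scenario$depth_decay
  stopifnot(decay > 0, all(totals > 0))
  grid <- expand.grid(species = c("NH4", "NO3"), depth_layer = layers,
                      treatment = treatments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  layer_idx <- match(grid$depth_layer, layers)
  top <- ifelse(grid$species == "NH4",
                fracs[grid$treatment] * totals[grid$treatment],
                (1 - fracs[grid$treatment]) * totals[grid$treatment])
  conc <- top * decay^(layer_idx - 1) *
    lnorm_factor(nrow(grid), scenario$noise_cv %||% 0)
  out <- tibble::tibble(
    treatment = grid$treatment,
    depth_layer = factor(grid$depth_layer, levels = layers, ordered = TRUE),
    species = grid$species,
    concentration = conc)
  attr(out, "scenario") <- scenario
  attr(out, "seed") <- seed
  class(out) <- c("trial_table", class(out))
  out
}

#' Ammonium share of total mineral N in one layer
#'
#' Convenience summary used on soil-profile tables:
#' `100 * NH4 / (NH4 + NO3)` within one treatment and depth layer.
#'
#' @param table A soil-profile `trial_table`.
#' @param treatment Treatment label.
#' @param layer Depth-layer label (default the topsoil layer).
#' @return Percentage (0-100).
#' @export
ammonium_share <- function(table, treatment = "LN", layer = NULL) {
  stopifnot(is.data.frame(table),
            all(c("treatment", "depth_layer", "species", "concentration")
                %in% names(table)))
  if (is.null(layer)) layer <- levels(table$depth_layer)[1L]
  sub <- table[table$treatment == treatment & table$depth_layer == layer, ]
  nh4 <- sum(sub$concentration[sub$species == "NH4"])
  no3 <- sum(sub$concentration[sub$species == "NO3"])
  100 * nh4 / (nh4 + no3)
}
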