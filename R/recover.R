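#' Regression-endpoint percent change recovered from a trial table
#'
#' The generate -> analyze round trip for one dataset: subset one
#' treatment, regress the trait on RHL by OLS, and evaluate the percent
#' change of the prediction between the generator's RHL endpoints for that
#' treatment (stored by the generator as the realized per-treatment RHL
#' range that anchored the trait lines).
#'
#' @param table A `trial_table` from [gen_greenhouse()] or [gen_field()].
#' @param trait Trait column name.
#' @param treatment Treatment subset (default `"LN"`).
#' @return The percent change (numeric scalar).
#' @export
recover_endpoint_change <- function(table, trait, treatment = "LN") {
  stopifnot(inherits(table, "trial_table"), trait %in% names(table))
  sub <- table[table$treatment == treatment, ]
  fit <- fit_linear(sub$rhl_mm, sub[[trait]])
  ep <- attr(table, "rhl_endpoints")[[treatment]]
  percent_change_from_fit(fit, ep[["x_min"]], ep[["x_max"]])$value
}

#' Treatment percent difference recovered from a trial table
#'
#' @inheritParams recover_endpoint_change
#' @param ref,alt Reference and alternative treatment labels.
#' @return The percent difference of trait means (numeric scalar).
#' @export
recover_treatment_difference <- function(table, trait, ref = "HN",
                                         alt = "LN") {
  treatment_percent_difference(table, trait, ref, alt)$value
}

#' Average an effect-recovery statistic over generator seeds
#'
#' Regenerates a scenario under each seed and applies a recovery function;
#' the Monte-Carlo mean is what the acceptance analyses report for
#' stochastic effects.
#'
#' @param scenario Scenario name or `trial_scenario`.
#' @param seeds Integer vector of generator seeds.
#' @param fun Recovery function taking a `trial_table` and returning a
#'   scalar (e.g. `\(tab) recover_endpoint_change(tab, "shoot_g")`).
#' @param generator One of `"greenhouse"`, `"field"`, `"soil"`.
#' @return List with `mean`, `values` (per seed) and `n` (seed count).
#' @export
recover_over_seeds <- function(scenario, seeds, fun,
                               generator = c("greenhouse", "field", "soil")) {
  generator <- match.arg(generator)
  gen <- switch(generator, greenhouse = gen_greenhouse, field = gen_field,
                soil = gen_soil_profile)
  if (is.character(scenario)) scenario <- load_trial_scenario(scenario)
  values <- vapply(seeds, function(s) fun(gen(scenario, seed = s)),
                   numeric(1))
  list(mean = mean(values), values = values, n = length(seeds))
}

#' Full statistical report for one trial trait
#'
#' Runs the complete analysis chain on a trial table: blocked two-way
#' ANOVA (genotype, treatment, interaction, block), protected LSD letter
#' groupings over genotypes, per-treatment OLS of the trait on RHL with
#' endpoint percent change, and the treatment percent difference.
#'
#' @param table A `trial_table` (greenhouse or field).
#' @param trait Trait column name.
#' @param ref,alt Treatment labels for the main-effect percent difference.
#' @param alpha Protection/LSD level.
#' @return A `trial_analysis` list: `anova`, `lsd`, `fits` (per
#'   treatment), `endpoint_change` (per treatment, percent),
#'   `treatment_difference` (percent).
#' @export
analyze_trial <- function(table, trait, ref = "HN", alt = "LN",
                          alpha = 0.05) {
  stopifnot(inherits(table, "trial_table"), trait %in% names(table))
  unit_col <- if ("block" %in% names(table)) "block" else "rep"
  an <- two_way_block_anova(table, trait, genotype = "ril",
                            treatment = "treatment", block = unit_col)
  means <- tapply(table[[trait]], table$ril, mean)
  n_per <- nrow(table) / length(means)
  lsd <- protected_lsd(an, means, n_per, alpha = alpha, term = "genotype")
  treatments <- unique(table$treatment)
  fits <- lapply(treatments, function(tr) {
    sub <- table[table$treatment == tr, ]
    fit_linear(sub$rhl_mm, sub[[trait]])
  })
  names(fits) <- treatments
  ep <- attr(table, "rhl_endpoints")
  changes <- vapply(treatments, function(tr) {
    e <- if (!is.null(ep)) ep[[tr]] else
      c(x_min = min(table$rhl_mm[table$treatment == tr]),
        x_max = max(table$rhl_mm[table$treatment == tr]))
    tryCatch(percent_change_from_fit(fits[[tr]], e[["x_min"]],
                                     e[["x_max"]])$value,
             error = function(err) NA_real_)
  }, numeric(1))
  structure(
    list(trait = trait, anova = an, lsd = lsd, fits = fits,
         endpoint_change = changes,
         treatment_difference = recover_treatment_difference(table, trait,
                                                             ref, alt)),
    class = "trial_analysis")
}

#' @export
print.trial_analysis <- function(x, ...) {
  cat(sprintf("<trial_analysis> trait '%s'\n", x$trait))
  print(x$anova)
  cat(sprintf("Treatment difference: %+.1f %%\n", x$treatment_difference))
  cat("Endpoint percent change by treatment:\n")
  print(round(x$endpoint_change, 1))
  invisible(x)
}

#' Write a trial analysis as JSON
#'
#' @param analysis A `trial_analysis`.
#' @param path Output path.
#' @export
write_analysis_json <- function(analysis, path) {
  stopifnot(inherits(analysis, "trial_analysis"))
  fits <- lapply(analysis$fits, function(f) {
    list(coefficients = as.list(f$coefficients), r_squared = f$r_squared,
         slope_se = f$slope_se, p_value = f$p_value,
         x_range = as.list(stats::setNames(f$x_range, c("min", "max"))))
  })
  plain <- function(x) {
    out <- data.frame(lapply(as.list(x)[seq_along(x)], unname),
                      stringsAsFactors = FALSE, check.names = FALSE)
    names(out) <- names(x)
    out
  }
  jsonlite::write_json(
    list(trait = analysis$trait,
         anova = plain(analysis$anova),
         lsd = c(list(protected = attr(analysis$lsd, "protected"),
                      lsd = attr(analysis$lsd, "lsd"),
                      omnibus_p = attr(analysis$lsd, "omnibus_p")),
                 list(groups = plain(analysis$lsd))),
         fits = fits,
         endpoint_change_pct = as.list(analysis$endpoint_change),
         treatment_difference_pct = analysis$treatment_difference),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
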