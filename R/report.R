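#' Figure-style report of a factorial sweep
#'
#' Renders uptake against root hair length, one panel per hair density x N
#' rate combination with one curve (quadratic fit) per transpiration
#' level, and writes the plotted values of every panel to CSV so the
#' figures are exactly replayable from text. Images are written only when
#' `render = TRUE`.
#'
#' @param sweep A `sweep_table` from [run_sweep()].
#' @param dir Output directory (created if needed).
#' @param render Also write a PNG of the panel grid?
#' @return A `report_bundle`: list with `plot` (a ggplot), `csv` (paths of
#'   the per-panel CSVs) and `panel_count`.
#' @export
report_sweep <- function(sweep, dir, render = FALSE) {
  stopifnot(inherits(sweep, "data.frame"))
  if (nrow(sweep) == 0L) stop("Empty sweep table.", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  panels <- unique(sweep[, c("rhd_per_cm", "n_kg_ha")])
  csvs <- character(0)
  for (p in seq_len(nrow(panels))) {
    sub <- sweep[sweep$rhd_per_cm == panels$rhd_per_cm[p] &
                   sweep$n_kg_ha == panels$n_kg_ha[p], ]
    f <- file.path(dir, sprintf("panel_rhd%s_n%s.csv", panels$rhd_per_cm[p],
                                panels$n_kg_ha[p]))
    utils::write.csv(as.data.frame(sub), f, row.names = FALSE)
    csvs <- c(csvs, f)
  }
  plt <- ggplot2::ggplot(
    sweep,
    ggplot2::aes(x = .data$rhl_mm, y = .data$uptake_umol,
                 colour = factor(.data$transpiration_pct))) +
    ggplot2::geom_point() +
    (if (length(unique(sweep$rhl_mm)) >= 3)
      ggplot2::geom_smooth(method = "lm",
                           formula = y ~ x + I(x^2), se = FALSE)
     else NULL) +
    ggplot2::facet_grid(rhd_per_cm ~ n_kg_ha,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Root hair length (mm)",
                  y = "Cumulative N uptake (umol)",
                  colour = "Transpiration (%)") +
    ggplot2::theme_bw()
  if (render) {
    ggplot2::ggsave(file.path(dir, "sweep_panels.png"), plt,
                    width = 3 + 2.2 * length(unique(sweep$n_kg_ha)),
                    height = 2 + 2 * length(unique(sweep$rhd_per_cm)),
                    dpi = 150)
  }
  structure(list(plot = plt, csv = csvs, panel_count = nrow(panels)),
            class = "report_bundle")
}

#' Figure-style report of a trait-on-RHL regression by treatment
#'
#' Scatter of the trait against RHL with per-treatment OLS lines (the
#' layout in which trial regressions are usually shown), plus a CSV of the
#' plotted values.
#'
#' @param table A `trial_table`.
#' @param trait Trait column.
#' @param dir Output directory.
#' @param render Write a PNG too?
#' @return A `report_bundle`.
#' @export
report_regression <- function(table, trait, dir, render = FALSE) {
  stopifnot(inherits(table, "data.frame"), trait %in% names(table))
  if (nrow(table) == 0L) stop("Empty trial table.", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f <- file.path(dir, sprintf("regression_%s.csv", trait))
  keep <- intersect(c("ril", "block", "rep", "treatment", "rhl_mm", trait),
                    names(table))
  utils::write.csv(as.data.frame(table)[, keep], f, row.names = FALSE)
  plt <- ggplot2::ggplot(
    table, ggplot2::aes(x = .data$rhl_mm, y = .data[[trait]],
                        colour = .data$treatment)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Root hair length (mm)", y = trait,
                  colour = "N level") +
    ggplot2::theme_bw()
  if (render) {
    ggplot2::ggsave(file.path(dir, sprintf("regression_%s.png", trait)),
                    plt, width = 5, height = 4, dpi = 150)
  }
  structure(list(plot = plt, csv = f, panel_count = 1L),
            class = "report_bundle")
}

#' Run manifest for replayable outputs
#'
#' Records what produced a set of output files: the package version, the
#' command, a key-order-independent configuration hash, the seeds and the
#' paths. Replaying the command with the same configuration and seeds
#' reproduces the tabular outputs byte for byte.
#'
#' @param command Short command descriptor (e.g. `"sweep"`).
#' @param config The configuration object used.
#' @param seeds Integer vector of seeds involved.
#' @param inputs,outputs Character vectors of file paths.
#' @param path Optional path to also write the manifest JSON.
#' @return The manifest as a list (invisibly if `path` is given).
#' @export
run_manifest <- function(command, config, seeds, inputs = character(0),
                         outputs = character(0), path = NULL) {
  manifest <- list(
    tool = "rhizoN",
    version = as.character(utils::packageVersion("rhizoN")),
    command = command,
    config_hash = config_hash(config),
    seeds = as.integer(seeds),
    inputs = inputs,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(path)) {
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
    return(invisible(manifest))
  }
  manifest
}
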