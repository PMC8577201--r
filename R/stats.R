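#' Ordinary least-squares fit of a trait on root hair length
#'
#' Fits `y = a + b x` by OLS and returns the quantities the trial analyses
#' report: coefficients, R-squared, the slope standard error and its
#' two-sided t-test p-value, and the x range actually used (the default
#' endpoints for [percent_change_from_fit()]).
#'
#' @param x Numeric predictor, typically root hair length in mm.
#' @param y Numeric response (a shoot trait, N content, yield, ...).
#' @return An object of class `regression_fit`: a list with elements
#'   `coefficients` (named `a`, `b`), `r_squared`, `df_residual`,
#'   `slope_se`, `p_value`, `x_range`, `order` (1) and `model` (the
#'   underlying `lm` fit).
#' @examples
#' fit <- fit_linear(c(0.2, 0.5, 0.8, 1.0), c(1.1, 2.0, 2.9, 3.5))
#' fit$coefficients
#' @export
fit_linear <- function(x, y) {
  check_xy(x, y, min_n = 3L)
  if (diff(range(x)) == 0) {
    stop("`x` is constant; the slope is not identifiable.", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # exact fits are routine here (zero-noise generators); the perfect-fit
  # warning from summary.lm is not informative
  sm <- suppressWarnings(summary(fit))
  structure(
    list(
      coefficients = c(a = unname(stats::coef(fit)[1L]),
                       b = unname(stats::coef(fit)[2L])),
      r_squared   = if (stats::var(y) == 0) 0 else sm$r.squared,
      df_residual = fit$df.residual,
      slope_se    = sm$coefficients["x", "Std. Error"],
      p_value     = sm$coefficients["x", "Pr(>|t|)"],
      x_range     = range(x),
      order       = 1L,
      model       = fit
    ),
    class = "regression_fit"
  )
}

#' Quadratic least-squares fit
#'
#' Fits `y = a + b x + c x^2`, the model used to summarise simulated
#' uptake against root hair length across a sweep. Inference is reported
#' at the model level (overall F) rather than per coefficient.
#'
#' @inheritParams fit_linear
#' @return A `regression_fit` with coefficients `a`, `b`, `c`, `r_squared`,
#'   `df_residual`, `f_statistic`, `p_value` (model F-test), `x_range`,
#'   `order` (2) and `model`.
#' @export
fit_quadratic <- function(x, y) {
  check_xy(x, y, min_n = 4L)
  X <- cbind(1, x, x^2)
  if (qr(X)$rank < 3L) {
    stop("Quadratic design matrix is rank deficient (too few distinct x).",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x + I(x^2))
  sm <- suppressWarnings(summary(fit))
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1L], fstat[2L], fstat[3L], lower.tail = FALSE)
  structure(
    list(
      coefficients = c(a = unname(stats::coef(fit)[1L]),
                       b = unname(stats::coef(fit)[2L]),
                       c = unname(stats::coef(fit)[3L])),
      r_squared   = if (stats::var(y) == 0) 0 else sm$r.squared,
      df_residual = fit$df.residual,
      f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1L]),
      p_value     = unname(p),
      x_range     = range(x),
      order       = 2L,
      model       = fit
    ),
    class = "regression_fit"
  )
}

#' @export
print.regression_fit <- function(x, ...) {
  kind <- if (x$order == 2L) "quadratic" else "linear"
  cat(sprintf("<regression_fit> %s\n", kind))
  print(round(x$coefficients, 6))
  cat(sprintf("R-squared %.4f, residual df %d, p = %.4g\n",
              x$r_squared, x$df_residual, x$p_value))
  invisible(x)
}

#' Predict from a `regression_fit`
#'
#' @param object A `regression_fit`.
#' @param x Numeric values at which to evaluate the fitted curve.
#' @param ... Unused.
#' @export
predict.regression_fit <- function(object, x, ...) {
  co <- object$coefficients
  if (object$order == 2L) co["a"] + co["b"] * x + co["c"] * x^2
  else co["a"] + co["b"] * x
}

#' Percent change between regression predictions at two endpoints
#'
#' The trial analyses summarise a fitted trait-on-RHL regression as the
#' relative change in the predicted trait between the shortest and longest
#' root hairs observed: `100 * (yhat(x_max) - yhat(x_min)) / yhat(x_min)`.
#'
#' @param fit A `regression_fit`.
#' @param x_min,x_max Endpoints (same units as the fit's predictor). Default
#'   to the x range stored in the fit.
#' @return An object of class `percent_change`: list with `value` (percent),
#'   `endpoints`, `predictions` and the basis `fit`.
#' @export
percent_change_from_fit <- function(fit,
                                    x_min = fit$x_range[1L],
                                    x_max = fit$x_range[2L]) {
  stopifnot(inherits(fit, "regression_fit"))
  y0 <- unname(predict(fit, x_min))
  y1 <- unname(predict(fit, x_max))
  if (!is.finite(y0) || y0 <= 0) {
    stop(sprintf(
      "Baseline prediction at x_min = %g is %g; percent change requires a positive baseline.",
      x_min, y0), call. = FALSE)
  }
  structure(
    list(value = 100 * (y1 - y0) / y0,
         endpoints = c(x_min = x_min, x_max = x_max),
         predictions = c(y_min = y0, y_max = y1),
         fit = fit),
    class = "percent_change"
  )
}

#' @export
print.percent_change <- function(x, ...) {
  cat(sprintf("<percent_change> %+.1f %% over x in [%g, %g] (yhat %g -> %g)\n",
              x$value, x$endpoints[1L], x$endpoints[2L],
              x$predictions[1L], x$predictions[2L]))
  invisible(x)
}

#' Two-way blocked ANOVA for a balanced RIL trial
#'
#' Partitions the trait sum of squares of a balanced genotype x treatment
#' trial with complete blocks into genotype, treatment, interaction, block
#' and residual components, with F-tests against the residual mean square.
#' Blocks are treated as a fixed additive factor; for balanced complete
#' designs the genotype/treatment/interaction F-tests coincide with those
#' of the random-block mixed model.
#'
#' @param table A data frame with one row per plot.
#' @param trait Column name (string) of the response.
#' @param genotype,treatment,block Column names of the design factors.
#'   Defaults match the trial generators (`ril`, `treatment`, `block`).
#' @return An `anova_table`: a tibble with columns `term`, `df`, `sum_sq`,
#'   `mean_sq`, `statistic`, `p_value`, plus attributes `zero_variance`
#'   and `n_per_cell`.
#' @export
two_way_block_anova <- function(table, trait,
                                genotype = "ril", treatment = "treatment",
                                block = "block") {
  stopifnot(is.data.frame(table))
  for (col in c(trait, genotype, treatment, block)) {
    if (!col %in% names(table)) {
      stop(sprintf("Column '%s' not found in `table`.", col), call. = FALSE)
    }
  }
  y <- table[[trait]]
  g <- factor(table[[genotype]])
  t_ <- factor(table[[treatment]])
  b <- factor(table[[block]])
  if (nlevels(g) < 2L || nlevels(t_) < 2L) {
    stop("Need at least two levels of genotype and of treatment.",
         call. = FALSE)
  }
  counts <- table(g, t_, b)
  if (length(unique(as.vector(counts))) != 1L || any(counts == 0L)) {
    stop("Design is unbalanced: every genotype x treatment x block cell must have the same count.",
         call. = FALSE)
  }

  zero_var <- stats::var(y) == 0 || !is.finite(stats::var(y))
  fit <- stats::aov(y ~ b + g + t_ + g:t_)
  an <- summary(fit)[[1L]]
  rn <- trimws(rownames(an))
  pick <- function(nm) which(rn == nm)
  terms <- c(b = "b", genotype = "g", treatment = "t_",
             `genotype:treatment` = "g:t_", residual = "Residuals")
  out <- tibble::tibble(
    term = c("genotype", "treatment", "genotype:treatment", "block",
             "residual"),
    df = c(an[pick("g"), "Df"], an[pick("t_"), "Df"], an[pick("g:t_"), "Df"],
           an[pick("b"), "Df"], an[pick("Residuals"), "Df"]),
    sum_sq = c(an[pick("g"), "Sum Sq"], an[pick("t_"), "Sum Sq"],
               an[pick("g:t_"), "Sum Sq"], an[pick("b"), "Sum Sq"],
               an[pick("Residuals"), "Sum Sq"]),
    mean_sq = sum_sq / df
  )
  ms_res <- out$mean_sq[out$term == "residual"]
  out$statistic <- ifelse(out$term == "residual", NA_real_,
                          if (zero_var) NA_real_ else out$mean_sq / ms_res)
  out$p_value <- ifelse(
    is.na(out$statistic), NA_real_,
    stats::pf(out$statistic, out$df, out$df[out$term == "residual"],
              lower.tail = FALSE))
  attr(out, "zero_variance") <- zero_var
  attr(out, "n_per_cell") <- unname(counts[1L])
  attr(out, "trait") <- trait
  class(out) <- c("anova_table", class(out))
  out
}

#' Protected Fisher LSD groupings
#'
#' Applies Fisher's least significant difference only when the omnibus
#' F-test for the chosen term is significant at `alpha` ("protected" LSD,
#' D = alpha). Means are assigned letters by a descending insert-and-absorb
#' sweep; two levels share a letter iff their means differ by at most the
#' LSD. Differences exactly equal to the LSD count as non-significant.
#'
#' @param anova An `anova_table` from [two_way_block_anova()].
#' @param means Named numeric vector of level means for the term of
#'   interest.
#' @param n_per_level Number of observations behind each mean (scalar;
#'   balanced designs only).
#' @param alpha Significance level for both the protection test and the
#'   LSD, default 0.05.
#' @param term Which ANOVA row protects the comparisons (default
#'   `"genotype"`).
#' @return An `lsd_grouping`: tibble (`level`, `mean`, `group`) sorted by
#'   descending mean, with attributes `lsd`, `protected`, `alpha`,
#'   `omnibus_p`. When protection fails `group` is `NA` for every level.
#' @export
protected_lsd <- function(anova, means, n_per_level, alpha = 0.05,
                          term = "genotype") {
  stopifnot(inherits(anova, "anova_table"))
  if (is.null(names(means)) || anyNA(names(means)) ||
      any(names(means) == "")) {
    stop("`means` must be a fully named numeric vector.", call. = FALSE)
  }
  if (length(n_per_level) != 1L || n_per_level < 2L) {
    stop("`n_per_level` must be a single count >= 2 (balanced designs).",
         call. = FALSE)
  }
  row <- anova[anova$term == term, ]
  if (nrow(row) != 1L) {
    stop(sprintf("Term '%s' not present in the ANOVA table.", term),
         call. = FALSE)
  }
  df_res <- anova$df[anova$term == "residual"]
  ms_res <- anova$mean_sq[anova$term == "residual"]
  omnibus_p <- row$p_value
  protected <- is.finite(omnibus_p) && omnibus_p < alpha
  lsd <- stats::qt(1 - alpha / 2, df_res) * sqrt(2 * ms_res / n_per_level)

  ord <- order(means, decreasing = TRUE)
  sorted <- means[ord]
  groups <- rep(NA_character_, length(sorted))
  if (protected) {
    groups <- lsd_letters(sorted, lsd)
  }
  out <- tibble::tibble(level = names(sorted), mean = unname(sorted),
                        group = groups)
  attr(out, "lsd") <- lsd
  attr(out, "protected") <- protected
  attr(out, "alpha") <- alpha
  attr(out, "omnibus_p") <- omnibus_p
  class(out) <- c("lsd_grouping", class(out))
  out
}

# Letter assignment for means sorted descending: from each index take the
# maximal run of means within `lsd` of it; runs whose end does not extend a
# previous run are absorbed; each surviving run contributes one letter.
lsd_letters <- function(sorted_means, lsd) {
  k <- length(sorted_means)
  run_end <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && (sorted_means[i] - sorted_means[j + 1L]) <= lsd) {
      j <- j + 1L
    }
    run_end[i] <- j
  }
  letters_out <- rep("", k)
  lab <- 0L
  last_end <- 0L
  for (i in seq_len(k)) {
    if (run_end[i] > last_end || i == 1L) {
      lab <- lab + 1L
      idx <- i:run_end[i]
      letters_out[idx] <- paste0(letters_out[idx], make_letter(lab))
      last_end <- run_end[i]
    }
  }
  letters_out
}

make_letter <- function(i) {
  if (i <= 26L) letters[i] else paste0(letters[(i - 1L) %/% 26L],
                                       letters[(i - 1L) %% 26L + 1L])
}

#' Percent difference between two treatment means
#'
#' `100 * (mean(alt) - mean(ref)) / mean(ref)` for a trait, the form in
#' which N-stress main effects are reported (e.g. low N reduced shoot
#' biomass by 45 percent relative to high N).
#'
#' @param table Data frame with one row per plot.
#' @param trait Response column name.
#' @param ref_level,alt_level Treatment labels; `ref_level` is the
#'   denominator.
#' @param treatment Treatment column name (default `"treatment"`).
#' @return A `percent_change` with `value` in percent and the two means in
#'   `predictions`.
#' @export
treatment_percent_difference <- function(table, trait, ref_level, alt_level,
                                         treatment = "treatment") {
  stopifnot(is.data.frame(table), trait %in% names(table),
            treatment %in% names(table))
  tr <- table[[treatment]]
  if (!ref_level %in% tr) stop(sprintf("Level '%s' absent.", ref_level),
                               call. = FALSE)
  if (!alt_level %in% tr) stop(sprintf("Level '%s' absent.", alt_level),
                               call. = FALSE)
  m_ref <- mean(table[[trait]][tr == ref_level])
  m_alt <- mean(table[[trait]][tr == alt_level])
  if (m_ref == 0) stop("Reference mean is zero; percent difference undefined.",
                       call. = FALSE)
  structure(
    list(value = 100 * (m_alt - m_ref) / m_ref,
         endpoints = c(ref = ref_level, alt = alt_level),
         predictions = c(mean_ref = m_ref, mean_alt = m_alt),
         fit = NULL),
    class = "percent_change"
  )
}

check_xy <- function(x, y, min_n) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("`x` and `y` must be numeric.", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length.", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) stop("Missing values are not allowed.",
                                 call. = FALSE)
  if (length(x) < min_n) {
    stop(sprintf("Need at least %d points.", min_n), call. = FALSE)
  }
  invisible(TRUE)
}
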