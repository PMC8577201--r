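test_that("fit_linear reproduces exact lines and flags degenerate input", {
  fit <- fit_linear(c(0, 1, 2, 3), c(1, 3, 5, 7))  # y = 1 + 2x
  expect_equal(unname(fit$coefficients), c(1, 2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$x_range, c(0, 3))

  flat <- fit_linear(c(0, 1, 2, 3), rep(4, 4))
  expect_equal(unname(flat$coefficients[["b"]]), 0)
  expect_equal(flat$r_squared, 0)

  expect_error(fit_linear(rep(1, 5), 1:5), "constant")
  expect_error(fit_linear(1:2, 1:2), "at least 3")
})

test_that("fit_linear and fit_quadratic match the normal-equations oracle", {
  for (s in 1:25) {
    set.seed(s)
    x <- runif(10, 0, 2)
    y <- 1 + 0.5 * x + rnorm(10)
    fit <- fit_linear(x, y)
    or <- ols_oracle(x, y, 1L)
    expect_equal(unname(fit$coefficients), or$beta, tolerance = 1e-10)
    expect_equal(fit$r_squared, or$r_squared, tolerance = 1e-10)
    expect_equal(fit$slope_se, or$slope_se, tolerance = 1e-10)

    qfit <- fit_quadratic(x, y)
    orq <- ols_oracle(x, y, 2L)
    expect_equal(unname(qfit$coefficients), orq$beta, tolerance = 1e-10)
    expect_equal(qfit$r_squared, orq$r_squared, tolerance = 1e-10)
    # nesting: the quadratic can only explain more
    expect_gte(qfit$r_squared, fit$r_squared - 1e-12)
  }
})

test_that("fit_quadratic recovers a pure parabola and rejects rank-deficient x", {
  x <- c(-2, -1, 0, 1, 2)
  fit <- fit_quadratic(x, x^2)
  expect_equal(unname(fit$coefficients), c(0, 0, 1), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_error(fit_quadratic(c(1, 1, 2, 2), c(1, 2, 3, 4)), "rank deficient")
})

test_that("percent change from a fit follows the endpoint formula", {
  fit <- fit_linear(c(0, 0.5, 1), c(1, 2, 3))  # y = 1 + 2x
  pc <- percent_change_from_fit(fit, 0, 1)
  expect_equal(pc$value, 200)  # 1 -> 3

  flat <- fit_linear(c(0, 0.5, 1), c(2, 2, 2))
  expect_equal(percent_change_from_fit(flat, 0, 1)$value, 0)

  # scale invariance: doubling a and b leaves the percent unchanged
  fit2 <- fit_linear(c(0, 0.5, 1), 2 * c(1, 2, 3))
  expect_equal(percent_change_from_fit(fit2, 0, 1)$value, 200)

  neg <- fit_linear(c(0, 0.5, 1), c(-1, 0, 1))
  expect_error(percent_change_from_fit(neg, 0, 1), "positive baseline")
})

test_that("blocked two-way ANOVA matches the direct sum-of-squares oracle", {
  # additive synthetic trait with known factor effects, no noise
  d <- expand.grid(ril = paste0("G", 1:4), treatment = c("HN", "LN"),
                   block = 1:3, stringsAsFactors = FALSE)
  g_eff <- c(G1 = 0, G2 = 1, G3 = 2, G4 = 5)
  t_eff <- c(HN = 0, LN = -2)
  b_eff <- c(1, 0, -1)
  d$y <- 10 + g_eff[d$ril] + t_eff[d$treatment] + b_eff[d$block]
  an <- two_way_block_anova(d, "y")
  or <- anova_ss_oracle(d$y, d$ril, d$treatment, d$block)
  expect_equal(an$sum_sq[an$term == "genotype"], or$genotype, tolerance = 1e-8)
  expect_equal(an$sum_sq[an$term == "treatment"], or$treatment, tolerance = 1e-8)
  expect_equal(an$sum_sq[an$term == "genotype:treatment"], or$interaction,
               tolerance = 1e-8)
  expect_equal(an$sum_sq[an$term == "block"], or$block, tolerance = 1e-8)
  expect_equal(sum(an$df), nrow(d) - 1)

  # row order invariance (noisy data so F ratios are well defined)
  dn <- random_balanced_trial(3)
  an_a <- two_way_block_anova(dn, "y")
  an_b <- two_way_block_anova(dn[sample(nrow(dn)), ], "y")
  expect_equal(as.data.frame(an_a), as.data.frame(an_b), tolerance = 1e-10)
})

test_that("ANOVA rejects unbalanced designs and flags zero variance", {
  d <- random_balanced_trial(1)
  expect_error(two_way_block_anova(d[-1, ], "y"), "unbalanced")
  d$y <- 5
  an <- two_way_block_anova(d, "y")
  expect_true(attr(an, "zero_variance"))
  expect_true(all(an$sum_sq < 1e-20))
  expect_true(all(is.na(an$statistic[an$term != "residual"])))
})

test_that("ANOVA sums of squares are additive on balanced data", {
  for (s in 1:10) {
    d <- random_balanced_trial(s)
    an <- two_way_block_anova(d, "y")
    ss_tot <- sum((d$y - mean(d$y))^2)
    expect_equal(sum(an$sum_sq), ss_tot, tolerance = 1e-8)
  }
})

test_that("protected LSD withholds letters without omnibus significance", {
  d <- random_balanced_trial(42)  # pure noise: genotype null true
  an <- two_way_block_anova(d, "y")
  means <- tapply(d$y, d$ril, mean)
  grp <- protected_lsd(an, means, n_per_level = 6)
  if (attr(an, "zero_variance") ||
      an$p_value[an$term == "genotype"] >= 0.05) {
    expect_false(attr(grp, "protected"))
    expect_true(all(is.na(grp$group)))
  }
  # forced non-significant omnibus
  an$p_value[an$term == "genotype"] <- 0.5
  grp2 <- protected_lsd(an, means, n_per_level = 6)
  expect_false(attr(grp2, "protected"))
  expect_true(all(is.na(grp2$group)))
})

test_that("LSD value and letter groupings match the pairwise oracle", {
  set.seed(7)
  for (case in 1:30) {
    d <- random_balanced_trial(case, n_g = 4L, n_t = 2L, n_b = 3L)
    # inject strong genotype separation in some cases
    if (case %% 2 == 0) {
      d$y <- d$y + c(G1 = 0, G2 = 3, G3 = 9, G4 = 30)[d$ril]
    }
    an <- two_way_block_anova(d, "y")
    means <- tapply(d$y, d$ril, mean)
    n_per <- 6
    grp <- protected_lsd(an, means, n_per_level = n_per)
    df_res <- an$df[an$term == "residual"]
    ms_res <- an$mean_sq[an$term == "residual"]
    lsd_hand <- qt(0.975, df_res) * sqrt(2 * ms_res / n_per)
    expect_equal(attr(grp, "lsd"), lsd_hand, tolerance = 1e-10)
    if (attr(grp, "protected")) {
      # exhaustive pairwise oracle: share a letter iff |diff| <= LSD
      for (i in seq_len(nrow(grp))) for (j in seq_len(nrow(grp))) {
        share <- length(intersect(strsplit(grp$group[i], "")[[1]],
                                  strsplit(grp$group[j], "")[[1]])) > 0
        expect_identical(share,
                         abs(grp$mean[i] - grp$mean[j]) <= lsd_hand + 1e-12,
                         label = sprintf("case %d pair %d-%d", case, i, j))
      }
    }
  }
})

test_that("treatment percent difference has the right value, sign and errors", {
  d <- data.frame(treatment = rep(c("HN", "LN"), each = 4),
                  y = c(rep(100, 4), rep(55, 4)))
  expect_equal(treatment_percent_difference(d, "y", "HN", "LN")$value, -45)
  expect_equal(treatment_percent_difference(d, "y", "LN", "HN")$value,
               100 * 45 / 55, tolerance = 1e-12)
  d$y <- 7
  expect_equal(treatment_percent_difference(d, "y", "HN", "LN")$value, 0)
  d$y <- 0
  expect_error(treatment_percent_difference(d, "y", "HN", "LN"), "zero")
  expect_error(treatment_percent_difference(d, "y", "HN", "XX"), "absent")
})
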