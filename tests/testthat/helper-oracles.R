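# Independent brute-force oracles used across test files. These never call
# the implementation paths they check.

# OLS by explicit normal equations
ols_oracle <- function(x, y, order = 1L) {
  X <- if (order == 2L) cbind(1, x, x^2) else cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  yhat <- X %*% beta
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - mean(y))^2)
  df <- length(y) - ncol(X)
  sigma2 <- ss_res / df
  covb <- sigma2 * solve(t(X) %*% X)
  list(beta = as.vector(beta),
       r_squared = if (ss_tot == 0) 0 else 1 - ss_res / ss_tot,
       slope_se = sqrt(covb[2L, 2L]),
       df = df)
}

# Direct sum-of-squares partition for a balanced genotype x treatment x
# block design, all effects against the grand mean
anova_ss_oracle <- function(y, g, t_, b) {
  gm <- mean(y)
  n <- length(y)
  ss_for <- function(f) {
    m <- tapply(y, f, mean)
    cnt <- tapply(y, f, length)
    sum(cnt * (m - gm)^2)
  }
  ss_g <- ss_for(g)
  ss_t <- ss_for(t_)
  ss_b <- ss_for(b)
  cellm <- tapply(y, list(g, t_), mean)
  cellc <- tapply(y, list(g, t_), length)
  ss_cells <- sum(cellc * (cellm - gm)^2)
  ss_gt <- ss_cells - ss_g - ss_t
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_g - ss_t - ss_gt - ss_b
  list(genotype = ss_g, treatment = ss_t, interaction = ss_gt,
       block = ss_b, residual = ss_res, total = ss_tot)
}

# 1-D diffusion by repeated explicit 3-point kernel with zero-flux ends,
# scalar loop
diffuse_1d_oracle <- function(C, alpha, n_steps) {
  n <- length(C)
  for (s in seq_len(n_steps)) {
    Cn <- C
    for (i in seq_len(n)) {
      left <- if (i > 1) C[i - 1] else C[i]
      right <- if (i < n) C[i + 1] else C[i]
      Cn[i] <- C[i] + alpha * (left - 2 * C[i] + right)
    }
    C <- Cn
  }
  C
}

# Brute-force per-day elongation ledger: expected total root length from
# the parameter set alone (no geometry). Axes elongate linearly from
# emergence; primordia appear when the parent axis length crosses
# multiples of the branching interval and emerge after the delay.
root_length_oracle <- function(params, t_end) {
  total <- 0
  main <- data.frame(
    class = c("primary", rep("seminal", params$seminal_count)),
    emerged = 0)
  for (i in seq_len(nrow(main))) {
    rate <- params$elongation_rate[[main$class[i]]]
    len <- rate * (t_end - main$emerged[i])
    total <- total + max(0, len)
    if (params$branching_interval_cm > 0 &&
        params$elongation_rate[["lateral"]] > 0) {
      k <- 1
      repeat {
        t_cross <- main$emerged[i] + k * params$branching_interval_cm / rate
        t_emerge <- t_cross + params$lateral_delay_d
        if (t_cross > t_end - 1e-9) break
        lat_len <- params$elongation_rate[["lateral"]] *
          max(0, t_end - t_emerge)
        total <- total + lat_len
        k <- k + 1
      }
    }
  }
  total
}

# random small balanced trial dataset for oracle comparisons
random_balanced_trial <- function(seed, n_g = 3L, n_t = 2L, n_b = 3L) {
  set.seed(seed)
  d <- expand.grid(ril = paste0("G", seq_len(n_g)),
                   treatment = paste0("T", seq_len(n_t)),
                   block = seq_len(n_b),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$y <- exp(stats::rnorm(nrow(d), 2, 0.5))
  d
}
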