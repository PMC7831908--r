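# Independent brute-force oracles (plain sums, no modelling functions) and
# shared fixture configurations.

noise_free_config <- function(seed = 7, ...) {
  simulation_config(seed = seed, measurement_noise_cv = 0, ratio_noise_cv = 0,
                    ratio_genotype_cv = 0, block_effect_sd = 0, ...)
}

# OLS of y on x by the normal equations, with R^2 and the two-sided slope p.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- 1 - ss_res / ss_tot
  se_slope <- sqrt(ss_res / (n - 2) / sxx)
  tval <- slope / se_slope
  list(slope = slope, intercept = intercept, r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
       p = 2 * stats::pt(-abs(tval), n - 2))
}

# Pearson r and its two-sided p from the t distribution on n - 2 df.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), n - 2))
}

# One-way ANOVA by explicit sums of squares.
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw)
}

# RMA slope by explicit sums: sign(Sxy) * sqrt(Syy / Sxx).
oracle_rma <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sign(sxy) * sqrt(syy / sxx)
}

# Random valid interval summary for decomposition-identity checks.
random_interval <- function() {
  t1 <- runif(1, 1, 10)
  t2 <- t1 + runif(1, 1, 20)
  w1 <- runif(1, 10, 100)
  w2 <- w1 * exp(runif(1, 0.05, 2))
  a1 <- runif(1, 1, 30)
  a2 <- a1 * exp(runif(1, 0.05, 2))
  np1 <- runif(1, 0.5, 5)
  np2 <- np1 * exp(runif(1, 0.05, 2))
  interval_summary(t1, t2, mean_lnW1 = log(w1), mean_lnW2 = log(w2),
                   mean_A1 = a1, mean_A2 = a2,
                   mean_Np1 = np1, mean_Np2 = np2)
}
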