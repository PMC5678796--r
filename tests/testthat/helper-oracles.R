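# Independent oracles used across the suite. These never call the code paths
# they check.

# Closed-form log odds ratio and SE of a 2x2 table (a,b = cases/non-cases in
# carriers; c,d in non-carriers).
oracle_logor_2x2 <- function(a, b, c, d) {
  list(beta = log((a / b) / (c / d)), se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# OLS slope/SE by the normal equations, independent of lm/glm machinery.
oracle_ols <- function(g, y) {
  n <- length(g)
  sxx <- sum((g - mean(g))^2)
  beta <- sum((g - mean(g)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(g)
  rss <- sum((y - alpha - beta * g)^2)
  list(beta = beta, se = sqrt(rss / (n - 2) / sxx))
}

# Analytic two-group Wald power for a continuous outcome under dominant
# coding: carrier fraction f = 1 - (1 - maf)^2, slope b1, residual SD sigma.
oracle_power_continuous <- function(n, b1, sigma, maf, alpha = 0.05) {
  f <- 1 - (1 - maf)^2
  pnorm(abs(b1) * sqrt(n * f * (1 - f)) / sigma - qnorm(1 - alpha / 2))
}

# Invert the analytic power formula for the n reaching a target power.
oracle_n_continuous <- function(b1, sigma, maf, target = 0.8, alpha = 0.05) {
  f <- 1 - (1 - maf)^2
  ((qnorm(1 - alpha / 2) + qnorm(target)) * sigma / abs(b1))^2 / (f * (1 - f))
}

# Expected additive-coding slope when the truth is a dominant effect b1:
# least-squares projection of the carrier indicator D = 1{A >= 1} onto the
# allele count A under HWE gives slope b1 * Cov(D, A) / Var(A) = b1 * (1 - p).
# (Cov = 2p(1-p)^2, Var = 2p(1-p).)
oracle_attenuated_slope <- function(b1, maf) b1 * (1 - maf)

base_binary_scenario <- function(...) {
  args <- utils::modifyList(list(
    maf = 0.1, effect_size = 1.5, outcome_type = "binary", n = 3000,
    true_model = "dominant_binary", prevalence = 0.1, baseline_or = 10,
    alpha = 0.05, target_power = 0.8, seed = 101L), list(...))
  do.call(scenario_config, args)
}

base_continuous_scenario <- function(...) {
  args <- utils::modifyList(list(
    maf = 0.1, effect_size = 0.3, outcome_type = "continuous", n = 600,
    true_model = "dominant_binary", trait_sd = 1, alpha = 0.05,
    target_power = 0.8, seed = 101L), list(...))
  do.call(scenario_config, args)
}
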