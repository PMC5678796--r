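# Synthetic-data core: alleles, genotypes, codings, outcome models.

test_that("allele simulation matches Bernoulli(MAF) and is seed-stable", {
  set.seed(11)
  n <- 100000
  al <- simulate_alleles(n, 0.1)
  tol <- 3 * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(mean(al$alleleA) - 0.1), tol)
  expect_lt(abs(mean(al$alleleB) - 0.1), tol)
  expect_true(all(al$alleleA %in% 0:1))

  set.seed(42)
  a1 <- simulate_alleles(50, 0.3)
  set.seed(42)
  a2 <- simulate_alleles(50, 0.3)
  expect_identical(a1, a2)

  expect_error(simulate_alleles(10, 0), "maf")
  expect_error(simulate_alleles(10, 1), "maf")
})

test_that("genotypes are the elementwise allele sum with the stated codes", {
  expect_identical(combine_alleles(c(0, 0, 1), c(0, 1, 1)), c(0L, 1L, 2L))
  expect_identical(combine_alleles(rep(0, 5), rep(0, 5)), rep(0L, 5))
  expect_error(combine_alleles(c(0, 1), c(1, 1, 0)), "length")
  expect_error(combine_alleles(c(0, 2), c(0, 0)), "only 0 and 1")
})

test_that("allele pairs reproduce Hardy-Weinberg genotype frequencies", {
  n <- 100000
  for (p in c(0.008, 0.025, 0.1)) {
    set.seed(1000 + round(p * 1000))
    al <- simulate_alleles(n, p)
    ac <- combine_alleles(al$alleleA, al$alleleB)
    expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    observed <- tabulate(ac + 1L, 3L) / n
    for (k in 1:3) {
      tol <- 3 * sqrt(expected[k] * (1 - expected[k]) / n)
      expect_lt(abs(observed[k] - expected[k]), tol,
                label = sprintf("genotype %d at p=%g", k - 1, p))
    }
  }
})

test_that("genotype coding: dominant collapses carriers, additive is identity", {
  expect_equal(code_genotype(c(0, 1, 2), "dominant_binary"), c(0, 1, 1))
  expect_equal(code_genotype(c(0, 1, 2), "additive"), c(0, 1, 2))
  expect_equal(code_genotype(rep(0, 4), "dominant_binary"), rep(0, 4))
  expect_equal(code_genotype(rep(0, 4), "additive"), rep(0, 4))
  expect_error(code_genotype(c(0, 3), "additive"), "0, 1, 2")
  expect_error(code_genotype(c(0, 1), "recessive"), "unknown")

  # coding consistency property: dominant == 1{additive >= 1} elementwise
  set.seed(5)
  for (i in 1:20) {
    ac <- sample(0:2, 50, replace = TRUE)
    expect_equal(code_genotype(ac, "dominant_binary"),
                 as.numeric(code_genotype(ac, "additive") >= 1))
  }
})

test_that("logistic intercept is the log-odds of prevalence", {
  expect_equal(beta0_from_prevalence(0.5), 0)
  expect_equal(beta0_from_prevalence(0.1), -2.19722, tolerance = 1e-5)
  for (p in c(0.01, 0.2, 0.7)) {
    expect_equal(plogis(beta0_from_prevalence(p)), p, tolerance = 1e-12)
  }
  expect_error(beta0_from_prevalence(0), "prevalence")
  expect_error(beta0_from_prevalence(1), "prevalence")
})

test_that("subject-effect SD realizes the 95th-vs-5th percentile odds contrast", {
  expect_equal(subject_effect_sd(1), 0)
  expect_equal(subject_effect_sd(10), 0.69994, tolerance = 1e-5)
  # algebraic round trip: the odds ratio between the 95th and 5th percentile
  # of N(0, sd^2) on the log-odds scale is exactly the baseline OR
  for (B in c(2, 10, 20)) {
    sd_b <- subject_effect_sd(B)
    expect_equal(exp(qnorm(0.95, 0, sd_b) - qnorm(0.05, 0, sd_b)), B,
                 tolerance = 1e-12)
  }
  expect_error(subject_effect_sd(0.5), "baseline_or")
})

test_that("binary outcomes follow expit(LP) frequencies", {
  n <- 100000
  # null effect at prevalence 0.1: case fraction = prevalence
  set.seed(21)
  y <- simulate_binary_outcome(rep(0, n), beta0_from_prevalence(0.1), 0, 0)
  expect_true(all(y %in% 0:1))
  expect_lt(abs(mean(y) - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  # all carriers, OR 2 on top of prevalence 0.1: expit(-2.19722 + ln 2)
  set.seed(22)
  y2 <- simulate_binary_outcome(rep(1, n), beta0_from_prevalence(0.1),
                                log(2), 0)
  mu <- 0.18182
  expect_lt(abs(mean(y2) - mu), 3 * sqrt(mu * (1 - mu) / n))

  expect_error(simulate_binary_outcome(0:1, 0, 0, -1), "subject_sd")
})

test_that("continuous outcomes are Gaussian around the linear predictor", {
  # noiseless limit is the linear predictor itself
  expect_equal(simulate_continuous_outcome(c(0, 1, 2), 0, 1, 0), c(0, 1, 2))

  n <- 100000
  set.seed(31)
  y <- simulate_continuous_outcome(rep(0, n), 0, 0, 1)
  expect_lt(abs(sd(y) - 1), 0.02)

  # carriers vs non-carriers differ by ~ beta1 under dominant coding
  set.seed(32)
  g <- as.numeric(combine_alleles(rbinom(n, 1, 0.2), rbinom(n, 1, 0.2)) >= 1)
  y2 <- simulate_continuous_outcome(g, 1, 0.5, 1)
  expect_equal(mean(y2[g == 1]) - mean(y2[g == 0]), 0.5, tolerance = 0.02)

  expect_error(simulate_continuous_outcome(0:1, 0, 1, -0.1), "trait_sd")
})

test_that("simulate_cohort is reproducible and honors both codings", {
  cfg <- scenario_config(maf = 0.2, effect_size = 1.5,
                         outcome_type = "binary", n = 400,
                         true_model = "dominant_binary",
                         analysis_model = "additive", seed = 9L)
  c1 <- simulate_cohort(cfg, seed = cfg$seed)
  c2 <- simulate_cohort(cfg, seed = cfg$seed)
  expect_identical(c1, c2)
  expect_true(all(c1$allele_count %in% 0:2))
  expect_true(all(c1$g_true %in% 0:1))             # dominant coding
  expect_identical(c1$g_analysis, as.numeric(c1$allele_count)) # additive
  expect_true(all(c1$outcome %in% 0:1))

  df <- as.data.frame(c1)
  expect_named(df, c("id", "allele_count", "g_true", "g_analysis", "outcome"))
  expect_equal(nrow(df), 400)
})

test_that("scenario validation reports the offending field", {
  expect_error(scenario_config(maf = 1.5, effect_size = 1.2,
                               outcome_type = "binary"), "maf")
  expect_error(scenario_config(maf = 0.1, effect_size = -2,
                               outcome_type = "binary"), "effect_size")
  expect_error(scenario_config(maf = 0.1, effect_size = 1.2,
                               outcome_type = "binary", prevalence = 0),
               "prevalence")
  expect_error(scenario_config(maf = 0.1, effect_size = 1.2,
                               outcome_type = "binary", baseline_or = 0.9),
               "baseline_or")
  expect_error(scenario_config(maf = 0.1, effect_size = 0.3,
                               outcome_type = "continuous", trait_sd = 0),
               "trait_sd")
  expect_error(scenario_config(maf = 0.1, effect_size = 1.2,
                               outcome_type = "binary", alpha = 1), "alpha")
  expect_error(scenario_config(maf = 0.1, effect_size = 1.2,
                               outcome_type = "binary", reps = 1), "reps")
  # null continuous effect is a legal configuration (type-I studies)
  expect_s3_class(scenario_config(maf = 0.1, effect_size = 0,
                                  outcome_type = "continuous"),
                  "scenario_config")
})
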