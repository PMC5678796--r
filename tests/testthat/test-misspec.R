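# Paired dominant-truth vs additive-coding comparison.

test_that("paired comparison is bitwise reproducible and well-formed", {
  cfg <- base_continuous_scenario(n = 400, reps = 120, seed = 53L)
  c1 <- run_misspec_scenario(cfg, sample_size = FALSE)
  c2 <- run_misspec_scenario(cfg, sample_size = FALSE)
  expect_identical(as.data.frame(c1), as.data.frame(c2))

  df <- as.data.frame(c1)
  expect_equal(nrow(df), 2)
  expect_equal(df$arm, c("true", "misspec"))
  expect_identical(names(df), snpmisspec:::RESULTS_SCHEMA)

  expect_error(
    run_misspec_scenario(scenario_modify(cfg, true_model = "additive",
                                         analysis_model = "additive")),
    "dominant_binary")
})

test_that("additive coding attenuates a dominant continuous effect by 1 - MAF", {
  cfg <- base_continuous_scenario(effect_size = 0.5, n = 4000, reps = 300,
                                  seed = 59L)
  cmp <- run_misspec_scenario(cfg, sample_size = FALSE)
  expected <- oracle_attenuated_slope(0.5, 0.1)
  expect_lt(abs(cmp$mean_beta_misspec - expected), 3 * cmp$beta_se_misspec)
  # no shrinkage under the true coding
  expect_lt(abs(cmp$mean_beta_true - 0.5), 3 * cmp$beta_se_true)
  expect_lt(abs(cmp$shrinkage_true), 3 * cmp$beta_se_true / 0.5)
  # and the misspecified arm shrinks by about MAF
  expect_equal(cmp$shrinkage_misspec, 0.1,
               tolerance = 3 * cmp$beta_se_misspec / 0.5 + 0.01)
})

test_that("true-model analysis is at least as powerful as the additive recoding", {
  cmp <- run_misspec_scenario(base_continuous_scenario(effect_size = 0.4,
                                                       n = 500, reps = 500,
                                                       seed = 61L),
                              sample_size = FALSE)
  tol <- 2 * (cmp$power_true$mc_se + cmp$power_misspec$mc_se)
  expect_gte(cmp$power_true$power, cmp$power_misspec$power - tol)

  # degenerate limit: at very low MAF the codings differ only on the ~maf^2
  # homozygous carriers, so the two arms nearly coincide
  rare <- run_misspec_scenario(base_continuous_scenario(effect_size = 0.4,
                                                        maf = 0.008,
                                                        n = 2000, reps = 400,
                                                        seed = 67L),
                               sample_size = FALSE)
  expect_lt(abs(rare$power_true$power - rare$power_misspec$power),
            2 * (rare$power_true$mc_se + rare$power_misspec$mc_se) + 0.01)
})

test_that("binary effect estimates: heterogeneity attenuates, its absence does not", {
  # no heterogeneity: mean log-OR recovers the configured conditional log-OR
  none <- run_misspec_scenario(
    base_binary_scenario(baseline_or = 1, n = 20000, reps = 150, seed = 71L),
    sample_size = FALSE)
  expect_lt(abs(none$mean_beta_true - log(1.5)), 3 * none$beta_se_true)

  # baseline OR 10: unmodelled subject effect shrinks the marginal OR
  het <- run_misspec_scenario(
    base_binary_scenario(baseline_or = 10, n = 20000, reps = 150, seed = 73L),
    sample_size = FALSE)
  expect_lt(het$mean_effect_true, 1.5)
  expect_gt(het$shrinkage_true, 0)
  # the misspecified arm shrinks more than the true arm
  expect_gt(het$shrinkage_misspec, het$shrinkage_true)
})

test_that("MAF sweep emits one comparison per grid point in the fixed schema", {
  one <- run_maf_sweep(base_continuous_scenario(n = 300, reps = 80,
                                                seed = 79L),
                       maf_grid = 0.1, sample_size = FALSE)
  expect_equal(nrow(one), 2)
  expect_identical(names(one), snpmisspec:::RESULTS_SCHEMA)

  sweep <- run_maf_sweep(base_continuous_scenario(n = 300, reps = 80,
                                                  seed = 79L),
                         maf_grid = c(0.025, 0.1), sample_size = FALSE)
  expect_equal(nrow(sweep), 4)
  expect_equal(sweep$maf, rep(c(0.025, 0.1), each = 2))
  expect_length(attr(sweep, "comparisons"), 2)
  expect_error(run_maf_sweep(base_continuous_scenario(),
                             maf_grid = c(0.1, 0.025)))
})

test_that("effect sweep crosses grids and uses sensible defaults", {
  sw <- run_effect_sweep(base_continuous_scenario(n = 200, reps = 60,
                                                  seed = 83L),
                         effect_grid = c(0.3, 0.6), maf_grid = c(0.05, 0.2))
  expect_equal(nrow(sw), 2 * 2 * 2) # (maf x effect) cells, two arms each
  expect_setequal(unique(sw$effect_size), c(0.3, 0.6))
  expect_identical(names(sw), snpmisspec:::RESULTS_SCHEMA)
  expect_error(run_effect_sweep(base_continuous_scenario(),
                                effect_grid = 0.5), "at least two")

  # default grid is eight effect sizes (odds ratios for a binary outcome)
  expect_equal(snpmisspec:::run_effect_sweep_defaults("binary", 1),
               seq(1.1, 1.8, by = 0.1))
  expect_equal(snpmisspec:::run_effect_sweep_defaults("continuous", 2),
               seq(0.2, 1.6, by = 0.2))
})
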