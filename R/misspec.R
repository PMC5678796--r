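## The analysis proper: paired comparison of the correctly specified
## (dominant) analysis against the misspecified (additive) analysis of a
## truly dominant SNP, across MAF and effect-size grids.

#' Paired true-model vs misspecified-model comparison for one scenario
#'
#' For each replicate one cohort is generated under the dominant truth and
#' fitted twice: once with the dominant (carrier indicator) coding, once
#' with the additive (allele count) coding. The two arms therefore consume
#' identical simulated cohorts — the misspecification is a recoding of the
#' covariate, not a regeneration of the data. Optionally, the sample size
#' required to reach the target power is searched for under each coding;
#' the two searches share their RNG stream keyed on (seed, n), so they too
#' are paired wherever they evaluate the same n.
#'
#' Effect summaries: `mean_effect_*` is the mean over converged replicates
#' of `exp(beta_hat)` (an odds ratio) for binary outcomes, of `beta_hat` for
#' continuous ones. Shrinkage is defined on the coefficient scale,
#' \deqn{shrinkage = 1 - mean(\hat\beta) / \beta_{true},}
#' with \eqn{\beta_{true}} the configured TRUE-model effect (log-OR for
#' binary). A positive value is attenuation toward the null. Note the
#' additive arm's coefficient is per allele while the truth is per carrier,
#' so its shrinkage includes the coding mismatch by construction — that is
#' the quantity of interest.
#'
#' @param scenario a [scenario_config()] with
#'   `true_model = "dominant_binary"`.
#' @param sample_size if `TRUE` (default), also run the two sample-size
#'   searches.
#' @param reps replicates for the paired power/effect loop (defaults to
#'   `scenario$reps`).
#' @param reps_per_step replicates per sample-size-search evaluation.
#' @return a `misspec_comparison` with fields `scenario`, `power_true`,
#'   `power_misspec` ([estimate_power()] objects), `n_true`, `n_misspec`
#'   ([required_sample_size()] objects or `NULL`), `mean_effect_true`,
#'   `mean_effect_misspec`, `shrinkage_true`, `shrinkage_misspec`,
#'   `mean_beta_true`, `mean_beta_misspec`, `beta_se_true`,
#'   `beta_se_misspec` (MC standard errors of the mean coefficients).
#' @examples
#' cfg <- scenario_config(maf = 0.1, effect_size = 0.5,
#'                        outcome_type = "continuous", n = 500,
#'                        reps = 200, seed = 11)
#' run_misspec_scenario(cfg, sample_size = FALSE)
#' @export
run_misspec_scenario <- function(scenario, sample_size = TRUE,
                                 reps = scenario$reps,
                                 reps_per_step = 500L) {
  stopifnot(inherits(scenario, "scenario_config"))
  if (scenario$true_model != "dominant_binary") {
    stop("the misspecification study assumes `true_model = \"dominant_binary\"`",
         call. = FALSE)
  }
  arms <- c("dominant_binary", "additive")
  res <- mc_replicates(scenario, reps, scenario$seed, arms = arms)

  beta_true_scale <- scenario_beta1(scenario)
  summarize_arm <- function(r) {
    b <- r$beta[r$converged]
    mean_beta <- if (length(b)) mean(b) else NA_real_
    beta_se <- if (length(b) > 1L) sd(b) / sqrt(length(b)) else NA_real_
    list(
      power = power_estimate(mean(r$detected), reps,
                             as.integer(scenario$n), sum(!r$converged)),
      mean_beta = mean_beta,
      beta_se = beta_se,
      mean_effect = if (scenario$outcome_type == "binary") {
        if (length(b)) mean(exp(b)) else NA_real_
      } else {
        mean_beta
      },
      shrinkage = 1 - mean_beta / beta_true_scale
    )
  }
  st <- summarize_arm(res[[1L]])
  sm <- summarize_arm(res[[2L]])

  n_true <- n_misspec <- NULL
  if (sample_size) {
    n_true <- required_sample_size(
      scenario_modify(scenario, analysis_model = "dominant_binary"),
      reps_per_step = reps_per_step)
    n_misspec <- required_sample_size(
      scenario_modify(scenario, analysis_model = "additive"),
      reps_per_step = reps_per_step)
  }

  structure(list(
    scenario = scenario,
    power_true = st$power, power_misspec = sm$power,
    n_true = n_true, n_misspec = n_misspec,
    mean_effect_true = st$mean_effect, mean_effect_misspec = sm$mean_effect,
    mean_beta_true = st$mean_beta, mean_beta_misspec = sm$mean_beta,
    beta_se_true = st$beta_se, beta_se_misspec = sm$beta_se,
    shrinkage_true = st$shrinkage, shrinkage_misspec = sm$shrinkage,
    reps = reps
  ), class = "misspec_comparison")
}

#' @export
print.misspec_comparison <- function(x, ...) {
  s <- x$scenario
  cat(sprintf("<misspec_comparison> %s outcome, MAF %g, effect %g, n %d, %d reps\n",
              s$outcome_type, s$maf, s$effect_size, as.integer(s$n), x$reps))
  cat(sprintf("  power: true %.3f vs misspecified %.3f\n",
              x$power_true$power, x$power_misspec$power))
  if (!is.null(x$n_true)) {
    cat(sprintf("  n at %.0f%% power: true %d vs misspecified %d (x%.3f)\n",
                100 * s$target_power, x$n_true$n_required,
                x$n_misspec$n_required,
                x$n_misspec$n_required / x$n_true$n_required))
  }
  cat(sprintf("  mean effect: true %.4f vs misspecified %.4f (shrinkage %.3f vs %.3f)\n",
              x$mean_effect_true, x$mean_effect_misspec,
              x$shrinkage_true, x$shrinkage_misspec))
  invisible(x)
}

#' Tidy two-row summary of a comparison
#'
#' One row per arm (`arm = "true"` then `"misspec"`), in the fixed results
#' schema shared by all commands (see [write_results()]).
#'
#' @param x a `misspec_comparison`.
#' @param ... unused.
#' @export
as.data.frame.misspec_comparison <- function(x, ...) {
  s <- x$scenario
  binary <- s$outcome_type == "binary"
  row <- function(arm, pe, ss, mean_effect, shrinkage, nonconv) {
    data.frame(
      outcome_type = s$outcome_type, maf = s$maf,
      effect_size = s$effect_size,
      prevalence = if (binary) s$prevalence else NA_real_,
      baseline_or = if (binary) s$baseline_or else NA_real_,
      trait_sd = if (binary) NA_real_ else s$trait_sd,
      n = as.integer(s$n), alpha = s$alpha, target_power = s$target_power,
      reps = as.integer(x$reps), arm = arm,
      power = pe$power, mc_se = pe$mc_se,
      n_required = if (is.null(ss)) NA_integer_ else ss$n_required,
      mean_effect = mean_effect, shrinkage = shrinkage,
      n_nonconverged = as.integer(nonconv), seed = as.integer(s$seed),
      stringsAsFactors = FALSE
    )
  }
  rbind(
    row("true", x$power_true, x$n_true, x$mean_effect_true,
        x$shrinkage_true, x$power_true$n_nonconverged),
    row("misspec", x$power_misspec, x$n_misspec, x$mean_effect_misspec,
        x$shrinkage_misspec, x$power_misspec$n_nonconverged)
  )
}

#' Misspecification impact across a MAF grid
#'
#' Runs [run_misspec_scenario()] at each MAF of the grid (rare, low
#' frequency, common), holding the effect size and outcome model fixed: per
#' MAF it yields the sample-size pair at the target power, the power pair at
#' the fixed `base$n`, and the effect-size shrinkage pair.
#'
#' @param base a [scenario_config()] template
#'   (`true_model = "dominant_binary"`).
#' @param maf_grid MAFs in (0, 1), sorted ascending.
#' @param sample_size run the paired sample-size searches (default `TRUE`).
#' @param reps,reps_per_step see [run_misspec_scenario()].
#' @return a data.frame with two rows (arms) per MAF in the fixed results
#'   schema; the per-MAF `misspec_comparison` objects are attached as
#'   attribute `"comparisons"`.
#' @export
run_maf_sweep <- function(base, maf_grid = c(0.008, 0.025, 0.1),
                          sample_size = TRUE, reps = base$reps,
                          reps_per_step = 500L) {
  stopifnot(all(maf_grid > 0), all(maf_grid < 1),
            !is.unsorted(maf_grid, strictly = TRUE))
  comparisons <- lapply(seq_along(maf_grid), function(i) {
    sc <- scenario_modify(base, maf = maf_grid[i],
                          seed = derive_seed(base$seed, 1L, i))
    run_misspec_scenario(sc, sample_size = sample_size, reps = reps,
                         reps_per_step = reps_per_step)
  })
  out <- do.call(rbind, lapply(comparisons, as.data.frame))
  attr(out, "comparisons") <- comparisons
  out
}

## Default "eight effect sizes": OR 1.1..1.8 for binary outcomes, mean
## shifts of 0.1..0.8 trait SDs for continuous ones.
run_effect_sweep_defaults <- function(outcome_type, trait_sd = 1) {
  if (outcome_type == "binary") {
    seq(1.1, 1.8, by = 0.1)
  } else {
    seq(0.1, 0.8, by = 0.1) * trait_sd
  }
}

#' Effect-size shrinkage across effect and MAF grids
#'
#' For each (MAF, effect size) cell, runs the paired comparison (no
#' sample-size search) and reports the mean estimated effect under both
#' arms next to the configured effect — the configured value plays the role
#' of the "expected" effect. The default grids are a rare, a low-frequency
#' and a common SNP crossed with eight effect sizes: odds ratios 1.1 to 1.8
#' (step 0.1) for binary outcomes, mean shifts 0.1 to 0.8 trait SDs for
#' continuous ones.
#'
#' @param base a [scenario_config()] template.
#' @param effect_grid at least two effect sizes; `NULL` picks the default
#'   eight for `base$outcome_type`.
#' @param maf_grid MAFs in (0, 1).
#' @param reps replicates per cell.
#' @return a data.frame with two rows per (MAF, effect) cell in the fixed
#'   results schema (the `effect_size` column is the expected value;
#'   `mean_effect` and `shrinkage` carry the estimates).
#' @export
run_effect_sweep <- function(base, effect_grid = NULL,
                             maf_grid = c(0.008, 0.025, 0.1),
                             reps = base$reps) {
  if (is.null(effect_grid)) {
    effect_grid <- run_effect_sweep_defaults(base$outcome_type,
                                             base$trait_sd)
  }
  if (length(effect_grid) < 2L) {
    stop("`effect_grid` must contain at least two effect sizes",
         call. = FALSE)
  }
  stopifnot(all(maf_grid > 0), all(maf_grid < 1))
  cells <- expand.grid(effect = effect_grid, maf = maf_grid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sc <- scenario_modify(base, maf = cells$maf[i],
                          effect_size = cells$effect[i],
                          seed = derive_seed(base$seed, 2L, i))
    as.data.frame(run_misspec_scenario(sc, sample_size = FALSE,
                                       reps = reps))
  })
  do.call(rbind, rows)
}
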