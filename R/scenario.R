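#' Genetic model codings
#'
#' The two genotype codings supported by the calculator: `"dominant_binary"`
#' (complete dominance: carriers of at least one risk allele form a single
#' genotype class coded 1) and `"additive"` (genotype coded by the count of
#' risk alleles, 0/1/2).
#'
#' @export
GENETIC_MODELS <- c("dominant_binary", "additive")

#' Outcome types
#'
#' `"binary"` outcomes are Bernoulli draws from an expit-transformed linear
#' predictor (logistic model with a subject effect); `"continuous"` outcomes
#' are Gaussian around the linear predictor.
#'
#' @export
OUTCOME_TYPES <- c("binary", "continuous")

#' Declare a simulation scenario
#'
#' A `scenario_config` is the complete parameterization of one Monte-Carlo
#' power scenario: the genetics (MAF, true and analysis genotype codings),
#' the outcome model, and the inference settings.
#'
#' @param maf minor allele frequency, strictly inside (0, 1). The risk allele
#'   is the minor allele.
#' @param effect_size for binary outcomes, the odds ratio per unit of the
#'   TRUE-model coded genotype (must be positive; 1 is the null); for
#'   continuous outcomes, the mean shift per unit of the TRUE-model coded
#'   genotype (any real; 0 is the null).
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param n number of individuals per simulated cohort.
#' @param true_model genotype coding under which outcomes are generated.
#' @param analysis_model genotype coding used when fitting; defaults to
#'   `true_model` (correctly specified analysis).
#' @param prevalence disease prevalence, in (0, 1); sets the logistic
#'   intercept \eqn{\beta_0 = \log(prev / (1 - prev))}. Binary outcomes only.
#' @param baseline_or baseline odds ratio (>= 1) between an individual at the
#'   95th and one at the 5th percentile of unexplained population risk; sets
#'   the SD of the normal subject effect on the log-odds scale. Binary
#'   outcomes only. Set to 1 for no heterogeneity.
#' @param trait_sd residual SD of the continuous outcome around the linear
#'   predictor. Continuous outcomes only.
#' @param trait_mean intercept \eqn{\beta_0} of the continuous outcome
#'   (default 0; it does not affect the Wald test on the genotype slope).
#' @param alpha two-sided significance level of the Wald z test.
#' @param target_power target power for sample-size searches.
#' @param reps Monte-Carlo replicates per power estimate.
#' @param seed RNG seed for the scenario (integer).
#' @return an object of class `scenario_config` (a validated named list).
#' @examples
#' cfg <- scenario_config(maf = 0.1, effect_size = 1.5, outcome_type = "binary",
#'                        n = 3000, true_model = "dominant_binary")
#' cfg
#' @seealso [simulate_cohort()], [estimate_power()], [required_sample_size()]
#' @export
scenario_config <- function(maf,
                            effect_size,
                            outcome_type = c("binary", "continuous"),
                            n = 1000L,
                            true_model = c("dominant_binary", "additive"),
                            analysis_model = NULL,
                            prevalence = 0.1,
                            baseline_or = 10,
                            trait_sd = 1,
                            trait_mean = 0,
                            alpha = 0.05,
                            target_power = 0.80,
                            reps = 1000L,
                            seed = 42L) {
  outcome_type <- match.arg(outcome_type)
  true_model <- match.arg(true_model)
  if (is.null(analysis_model)) analysis_model <- true_model
  analysis_model <- match.arg(analysis_model, GENETIC_MODELS)

  cfg <- structure(list(
    n = n, maf = maf, true_model = true_model,
    analysis_model = analysis_model, outcome_type = outcome_type,
    effect_size = effect_size, prevalence = prevalence,
    baseline_or = baseline_or, trait_sd = trait_sd, trait_mean = trait_mean,
    alpha = alpha, target_power = target_power, reps = reps, seed = seed
  ), class = "scenario_config")
  validate_scenario_config(cfg)
}

#' @rdname scenario_config
#' @param x a `scenario_config`.
#' @export
validate_scenario_config <- function(x) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid `", field, "`: ", msg, call. = FALSE)
  }
  num1 <- function(v) length(v) == 1L && is.numeric(v) && is.finite(v)

  chk(num1(x$n) && x$n >= 1 && x$n == floor(x$n), "n",
      "must be a positive integer")
  chk(num1(x$maf) && x$maf > 0 && x$maf < 1, "maf",
      "must be strictly inside (0, 1); 0 or 1 would give a monomorphic SNP")
  chk(x$true_model %in% GENETIC_MODELS, "true_model",
      paste("must be one of", paste(GENETIC_MODELS, collapse = ", ")))
  chk(x$analysis_model %in% GENETIC_MODELS, "analysis_model",
      paste("must be one of", paste(GENETIC_MODELS, collapse = ", ")))
  chk(x$outcome_type %in% OUTCOME_TYPES, "outcome_type",
      paste("must be one of", paste(OUTCOME_TYPES, collapse = ", ")))
  if (x$outcome_type == "binary") {
    chk(num1(x$effect_size) && x$effect_size > 0, "effect_size",
        "must be a positive odds ratio for a binary outcome")
    chk(num1(x$prevalence) && x$prevalence > 0 && x$prevalence < 1,
        "prevalence", "must be strictly inside (0, 1)")
    chk(num1(x$baseline_or) && x$baseline_or >= 1, "baseline_or",
        "must be >= 1 (1 means no unexplained heterogeneity)")
  } else {
    chk(num1(x$effect_size), "effect_size",
        "must be a finite mean shift for a continuous outcome")
    chk(num1(x$trait_sd) && x$trait_sd > 0, "trait_sd", "must be positive")
    chk(num1(x$trait_mean), "trait_mean", "must be a finite real")
  }
  chk(num1(x$alpha) && x$alpha > 0 && x$alpha < 1, "alpha",
      "must be strictly inside (0, 1)")
  chk(num1(x$target_power) && x$target_power > 0 && x$target_power < 1,
      "target_power", "must be strictly inside (0, 1)")
  chk(num1(x$reps) && x$reps > 1 && x$reps == floor(x$reps), "reps",
      "must be an integer > 1")
  chk(num1(x$seed) && x$seed == floor(x$seed), "seed", "must be an integer")
  x
}

## TRUE-model effect on the linear-predictor scale (log-OR for binary).
scenario_beta1 <- function(cfg) {
  if (cfg$outcome_type == "binary") log(cfg$effect_size) else cfg$effect_size
}

## Is the configured effect the null?
scenario_is_null <- function(cfg) {
  scenario_beta1(cfg) == 0
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  outcome: %s | true model: %s | analysis model: %s\n",
              x$outcome_type, x$true_model, x$analysis_model))
  cat(sprintf("  n = %d, MAF = %g, effect_size = %g\n",
              as.integer(x$n), x$maf, x$effect_size))
  if (x$outcome_type == "binary") {
    cat(sprintf("  prevalence = %g, baseline OR = %g\n",
                x$prevalence, x$baseline_or))
  } else {
    cat(sprintf("  trait mean = %g, trait SD = %g\n",
                x$trait_mean, x$trait_sd))
  }
  cat(sprintf("  alpha = %g, target power = %g, reps = %d, seed = %d\n",
              x$alpha, x$target_power, as.integer(x$reps),
              as.integer(x$seed)))
  invisible(x)
}

## Clone a scenario with some fields replaced, re-validating.
scenario_modify <- function(cfg, ...) {
  repl <- list(...)
  out <- utils::modifyList(unclass(cfg), repl)
  validate_scenario_config(structure(out, class = "scenario_config"))
}
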