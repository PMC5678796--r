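## Synthetic-data core: alleles -> genotypes -> model coding -> outcome.
## All draws use the R global RNG; callers control seeding (see estimate_power
## for the per-replicate substream policy).

#' Simulate the two alleles of a bi-allelic SNP
#'
#' Draws the alleles on the two homologous chromosomes as independent
#' Bernoulli(`maf`) vectors: the wild allele is 0, the risk allele is 1.
#'
#' @param n number of individuals (>= 1).
#' @param maf minor allele frequency, strictly inside (0, 1).
#' @return a list with integer vectors `alleleA` and `alleleB`, each of
#'   length `n` with entries in \{0, 1\}.
#' @examples
#' set.seed(1)
#' al <- simulate_alleles(10, 0.2)
#' table(al$alleleA + al$alleleB)
#' @export
simulate_alleles <- function(n, maf) {
  stopifnot(length(n) == 1L, is.finite(n), n >= 1)
  if (!(length(maf) == 1L && is.finite(maf) && maf > 0 && maf < 1)) {
    stop("invalid `maf`: must be strictly inside (0, 1)", call. = FALSE)
  }
  list(alleleA = rbinom(n, 1L, maf), alleleB = rbinom(n, 1L, maf))
}

#' Combine two allele vectors into genotype risk-allele counts
#'
#' Elementwise sum of the two per-chromosome allele vectors: 0/0 -> 0,
#' 0/1 -> 1, 1/1 -> 2. Under Hardy-Weinberg equilibrium at allele frequency
#' p the three counts occur with frequencies \eqn{(1-p)^2}, \eqn{2p(1-p)},
#' \eqn{p^2}.
#'
#' @param alleleA,alleleB equal-length vectors with entries in \{0, 1\}.
#' @return an integer vector of allele counts in \{0, 1, 2\}.
#' @examples
#' combine_alleles(c(0, 0, 1), c(0, 1, 1))
#' @export
combine_alleles <- function(alleleA, alleleB) {
  if (length(alleleA) != length(alleleB)) {
    stop("allele vectors must have equal length", call. = FALSE)
  }
  if (!all(alleleA %in% c(0, 1)) || !all(alleleB %in% c(0, 1))) {
    stop("allele vectors must contain only 0 and 1", call. = FALSE)
  }
  as.integer(alleleA + alleleB)
}

#' Code genotypes under a genetic model
#'
#' Additive coding returns the allele count unchanged (0/1/2). Dominant
#' ("binary") coding collapses heterozygotes and homozygous carriers into a
#' single class: the covariate is the carrier indicator 1\{count >= 1\},
#' reflecting complete dominance where one risk allele confers the full
#' effect.
#'
#' @param allele_count vector with entries in \{0, 1, 2\}.
#' @param model `"dominant_binary"` or `"additive"`.
#' @return a numeric covariate vector (\{0, 1\} under dominant coding,
#'   \{0, 1, 2\} under additive).
#' @examples
#' code_genotype(c(0, 1, 2), "dominant_binary") # 0 1 1
#' code_genotype(c(0, 1, 2), "additive")        # 0 1 2
#' @export
code_genotype <- function(allele_count, model) {
  if (!all(allele_count %in% c(0, 1, 2))) {
    stop("allele_count entries must be in {0, 1, 2}", call. = FALSE)
  }
  if (!(length(model) == 1L && model %in% GENETIC_MODELS)) {
    stop("unknown genetic model: must be one of ",
         paste(GENETIC_MODELS, collapse = ", "), call. = FALSE)
  }
  switch(model,
         additive = as.numeric(allele_count),
         dominant_binary = as.numeric(allele_count >= 1))
}

#' Logistic intercept from disease prevalence
#'
#' \eqn{\beta_0 = \log(prev / (1 - prev))}, the log-odds of the disease
#' prevalence.
#'
#' @param prevalence probability strictly inside (0, 1).
#' @return the intercept on the log-odds scale.
#' @examples
#' beta0_from_prevalence(0.5) # 0
#' beta0_from_prevalence(0.1) # -2.197225
#' @export
beta0_from_prevalence <- function(prevalence) {
  if (!(length(prevalence) == 1L && is.finite(prevalence) &&
        prevalence > 0 && prevalence < 1)) {
    stop("invalid `prevalence`: must be strictly inside (0, 1)",
         call. = FALSE)
  }
  qlogis(prevalence)
}

#' Subject-effect SD from the baseline odds ratio
#'
#' The unexplained between-individual heterogeneity in disease risk is a
#' zero-mean normal term on the log-odds scale whose spread is parameterized
#' by the odds ratio `baseline_or` between an individual at the 95th and one
#' at the 5th percentile of population risk. Since those percentiles sit
#' \eqn{2 z_{0.95}} SDs apart, the SD is
#' \deqn{\sigma_{subject} = \log(baseline\_or) / (2 z_{0.95}),}
#' with \eqn{z_{0.95} = \Phi^{-1}(0.95) \approx 1.6448536}. The round trip
#' \eqn{\exp(2 z_{0.95} \sigma_{subject}) = baseline\_or} is exact.
#'
#' @param baseline_or odds ratio >= 1 (1 means no heterogeneity).
#' @return the nonnegative SD of the subject effect.
#' @examples
#' subject_effect_sd(1)  # 0
#' subject_effect_sd(10) # 0.699936
#' @export
subject_effect_sd <- function(baseline_or) {
  if (!(length(baseline_or) == 1L && is.finite(baseline_or) &&
        baseline_or >= 1)) {
    stop("invalid `baseline_or`: must be a finite value >= 1", call. = FALSE)
  }
  log(baseline_or) / (2 * qnorm(0.95))
}

#' Simulate a binary outcome from the logistic linear predictor
#'
#' Per individual: a subject effect \eqn{s \sim N(0, subject\_sd^2)} is
#' added to the linear predictor \eqn{LP = \beta_0 + \beta_1 g + s}; the
#' disease probability is \eqn{mu = expit(LP)}; the outcome is
#' Bernoulli(\eqn{mu}).
#'
#' @param g_coded genotype covariate vector (TRUE-model coding).
#' @param beta0 intercept on the log-odds scale (see
#'   [beta0_from_prevalence()]).
#' @param beta1_log_or genotype effect on the log-odds scale (log odds
#'   ratio per coded unit).
#' @param subject_sd SD of the subject effect (>= 0; see
#'   [subject_effect_sd()]).
#' @return an integer 0/1 outcome vector.
#' @export
simulate_binary_outcome <- function(g_coded, beta0, beta1_log_or,
                                    subject_sd = 0) {
  stopifnot(is.numeric(g_coded), length(subject_sd) == 1L)
  if (!(is.finite(subject_sd) && subject_sd >= 0)) {
    stop("invalid `subject_sd`: must be >= 0", call. = FALSE)
  }
  n <- length(g_coded)
  lp <- beta0 + beta1_log_or * g_coded
  if (subject_sd > 0) lp <- lp + rnorm(n, 0, subject_sd)
  if (any(!is.finite(lp))) {
    stop("non-finite linear predictor encountered", call. = FALSE)
  }
  rbinom(n, 1L, plogis(lp))
}

#' Simulate a continuous outcome around the linear predictor
#'
#' \eqn{y_i \sim N(\beta_0 + \beta_1 g_i, trait\_sd^2)}. There is no
#' subject effect for continuous outcomes: the residual SD already carries
#' all unexplained variation.
#'
#' @param g_coded genotype covariate vector (TRUE-model coding).
#' @param beta0 trait mean at genotype 0.
#' @param beta1 mean shift per coded genotype unit.
#' @param trait_sd residual SD (>= 0; 0 gives the noiseless limit, useful
#'   for testing).
#' @return a numeric outcome vector.
#' @export
simulate_continuous_outcome <- function(g_coded, beta0, beta1, trait_sd) {
  stopifnot(is.numeric(g_coded), length(trait_sd) == 1L)
  if (!(is.finite(trait_sd) && trait_sd >= 0)) {
    stop("invalid `trait_sd`: must be >= 0", call. = FALSE)
  }
  lp <- beta0 + beta1 * g_coded
  if (trait_sd == 0) return(lp)
  rnorm(length(g_coded), lp, trait_sd)
}

#' Simulate one cohort under a scenario
#'
#' Draws alleles at the scenario's MAF, codes the genotype under the TRUE
#' model (used to generate the outcome) and under the ANALYSIS model (used
#' for fitting), and simulates the outcome. Uses the global RNG; pass `seed`
#' for a self-contained reproducible draw.
#'
#' @param config a [scenario_config()].
#' @param seed optional integer; if given, the cohort is drawn from a fresh
#'   L'Ecuyer-CMRG stream for that seed and the caller's RNG state is left
#'   untouched.
#' @return an object of class `snp_cohort`: a list with `allele_count`,
#'   `g_true`, `g_analysis`, `outcome`, `coding_true`, `coding_analysis`,
#'   `outcome_type`, `n`.
#' @examples
#' cfg <- scenario_config(maf = 0.1, effect_size = 1.5,
#'                        outcome_type = "binary", n = 500)
#' coh <- simulate_cohort(cfg, seed = 1)
#' table(coh$allele_count)
#' @export
simulate_cohort <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) {
    old <- rng_snapshot()
    on.exit(rng_restore(old))
    rng_set_state(rng_master_state(seed))
  }
  al <- simulate_alleles(config$n, config$maf)
  ac <- combine_alleles(al$alleleA, al$alleleB)
  g_true <- code_genotype(ac, config$true_model)
  g_analysis <- code_genotype(ac, config$analysis_model)
  outcome <- if (config$outcome_type == "binary") {
    simulate_binary_outcome(
      g_true,
      beta0 = beta0_from_prevalence(config$prevalence),
      beta1_log_or = log(config$effect_size),
      subject_sd = subject_effect_sd(config$baseline_or)
    )
  } else {
    simulate_continuous_outcome(
      g_true,
      beta0 = config$trait_mean,
      beta1 = config$effect_size,
      trait_sd = config$trait_sd
    )
  }
  structure(list(
    allele_count = ac, g_true = g_true, g_analysis = g_analysis,
    outcome = outcome, coding_true = config$true_model,
    coding_analysis = config$analysis_model,
    outcome_type = config$outcome_type, n = length(ac)
  ), class = "snp_cohort")
}

#' @export
print.snp_cohort <- function(x, ...) {
  cat(sprintf("<snp_cohort> n = %d, %s outcome, coding %s (truth %s)\n",
              x$n, x$outcome_type, x$coding_analysis, x$coding_true))
  cat("  genotype counts:",
      paste(sprintf("%d:%d", 0:2, tabulate(x$allele_count + 1L, 3L)),
            collapse = " "), "\n")
  invisible(x)
}

#' @export
as.data.frame.snp_cohort <- function(x, ...) {
  data.frame(id = seq_len(x$n), allele_count = x$allele_count,
             g_true = x$g_true, g_analysis = x$g_analysis,
             outcome = x$outcome)
}
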