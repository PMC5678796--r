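# snpmisspec

Simulation-based power and sample-size calculation for candidate-gene
association studies of a single bi-allelic SNP — and a paired quantification
of what it costs to analyse a truly **dominant** variant under the
conventional **additive** genotype coding.

## The problem

In association studies the mode of inheritance of a candidate variant is
rarely known, and the default is to code the genotype additively (0/1/2 risk
alleles). If the variant is actually dominant — one copy of the risk allele
confers the full effect — the additive coding assigns heterozygotes half the
risk they really carry. This misspecification costs statistical power,
inflates the sample size needed for a target power, and shrinks the estimated
effect toward the null. `snpmisspec` measures all three by Monte Carlo, for
binary (logistic) and continuous (Gaussian) outcomes, across minor allele
frequency (MAF) and effect-size grids.

## The model

Each simulated individual gets two independent Bernoulli(MAF) alleles;
their sum is the genotype count `A ∈ {0,1,2}` (Hardy–Weinberg equilibrium).
The dominant coding is the carrier indicator `D = 1{A ≥ 1}`, the additive
coding is `A` itself. Outcomes are generated from the linear predictor

    LP = β₀ + β₁ G + s,    G = TRUE-model coding of the genotype

* **binary**: `β₀ = logit(prevalence)`, `β₁ = log(OR)`, and
  `s ~ N(0, σ²_subject)` is a subject effect capturing unexplained
  heterogeneity in risk, parameterized by a *baseline odds ratio* `B` between
  the 95th and 5th population risk percentiles:
  `σ_subject = log(B) / (2 z₀.₉₅)`, `z₀.₉₅ = Φ⁻¹(0.95)`. The outcome is
  Bernoulli(expit(LP)).
* **continuous**: the outcome is `N(LP, σ²)` with a configurable trait SD
  (no subject effect).

Association is tested by the large-sample Wald z test on the genotype
coefficient of the appropriate GLM, two-sided at level α. Empirical power is
the fraction of replicates with `p < α`; the required sample size is found by
doubling-then-bisection on the Monte-Carlo power curve. In the
misspecification analysis the same simulated cohort is fitted twice —
dominant coding and additive coding — so the comparison is paired within
replicate.

## Worked example

```r
library(snpmisspec)

cfg <- scenario_config(maf = 0.1, effect_size = 1.5, outcome_type = "binary",
                       n = 3000, true_model = "dominant_binary",
                       prevalence = 0.1, baseline_or = 10, reps = 1000, seed = 42)

estimate_power(cfg)
#> <power_estimate> power = 0.800 (MC SE 0.0126), n = 3000, reps = 1000, non-converged = 0

run_misspec_scenario(cfg, sample_size = FALSE)
#> <misspec_comparison> binary outcome, MAF 0.1, effect 1.5, n 3000, 1000 reps
#>   power: true 0.800 vs misspecified 0.789
#>   mean effect: true 1.4688 vs misspecified 1.4033 (shrinkage 0.074 vs 0.182)
```

Reading the numbers: a common dominant SNP (MAF 0.1) with a carrier odds
ratio of 1.5 reaches 80.0% power at n = 3000 when analysed with the correct
carrier coding; recoding the same cohorts additively drops power to 78.9%
and shrinks the mean estimated odds ratio from 1.47 to 1.40. The true-coding
estimate itself sits below the configured OR of 1.5 (shrinkage 0.074 on the
log-OR scale) because the unmodelled subject effect (baseline OR 10)
attenuates the marginal odds ratio — an attenuation the calculator
reproduces deliberately, since real analyses cannot adjust for unmeasured
heterogeneity either.

Grid analyses and the sample-size search:

```r
run_maf_sweep(cfg, maf_grid = c(0.008, 0.025, 0.1))   # Fig.-2-style table
run_effect_sweep(cfg)                                 # Fig.-3-style table, 8 ORs x 3 MAFs
required_sample_size(cfg)                             # n for 80% power
```

## Command line

```sh
inst/cli/snpmisspec power       --config scenario.yaml --out power.csv
inst/cli/snpmisspec samplesize  --config scenario.yaml --out n.csv
inst/cli/snpmisspec maf-sweep   --config grid.yaml --out sweep.csv --plots
inst/cli/snpmisspec effect-sweep --config grid.yaml --out effects.csv
```

Configs are YAML or JSON (`maf_grid:`/`effect_grid:` expand to a scenario
grid); every run writes a fixed-schema CSV plus a JSON manifest with a config
hash, the seed and timestamps. `--dry-run` prints the expanded grid.

## Documentation

`vignettes/misspecification.Rmd` describes the model, the choice of every
default, what the synthetic cohorts do and do not emulate, and the numerical
decisions in the sample-size search.
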