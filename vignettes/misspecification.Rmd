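---
title: "Power, sample size and effect shrinkage when a dominant SNP is coded additively"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power, sample size and effect shrinkage when a dominant SNP is coded additively}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmisspec)
```

## The question

Candidate-gene studies usually code a SNP additively — 0, 1 or 2 copies of
the risk allele — because the true mode of inheritance is unknown. When the
variant is in fact completely dominant (one copy confers the full effect),
the additive coding assigns heterozygous carriers half the risk they really
have, and assigns homozygous carriers a genotype class of their own that the
truth does not distinguish. `snpmisspec` quantifies the consequences of that
coding error for three design quantities: empirical power at a fixed sample
size, the sample size required for a target power, and the estimated effect
size.

## The generative model

One scenario is one `scenario_config()`. A cohort of `n` individuals is
simulated as follows.

**Genotypes.** Two alleles per individual are drawn independently as
Bernoulli(MAF); their sum is the allele count in {0, 1, 2}, so genotype
frequencies follow Hardy–Weinberg equilibrium,
$((1-p)^2,\; 2p(1-p),\; p^2)$. The dominant ("binary") coding is the carrier
indicator $D = 1\{A \ge 1\}$; the additive coding is the count $A$ itself.
Real cohorts deviate from this idealization (inbreeding, population
structure, linkage disequilibrium with neighbouring variants, genotyping
error, covariates); none of those are modelled, so a green test here
establishes the behaviour of the coding error in the clean HWE single-SNP
world, not in the presence of confounding.

**Binary outcome.** The linear predictor is
$LP = \beta_0 + \beta_1 G + s$, with $\beta_0 = \mathrm{logit}(\text{prevalence})$
and $\beta_1$ the log odds ratio per unit of the TRUE-model coding. The
subject effect $s \sim N(0, \sigma_s^2)$ represents risk heterogeneity from
unmeasured determinants. It is parameterized by the *baseline odds ratio*
$B$: the odds of disease for someone at the 95th percentile of unexplained
risk relative to someone at the 5th. Because those percentiles are
$2 z_{0.95}$ standard deviations apart on the log-odds scale,

$$\sigma_s = \frac{\log B}{2\,z_{0.95}}, \qquad z_{0.95} = \Phi^{-1}(0.95) \approx 1.6448536 .$$

The displayed parameterization is sometimes written with a "variance of the
baseline OR" in the numerator; we use $\log B$, the unique choice for which
the 95th-vs-5th percentile odds contrast equals $B$ exactly —
`subject_effect_sd()` satisfies $\exp(2 z_{0.95} \sigma_s) = B$ to machine
precision, and the package treats that round trip as a tested invariant.
The outcome is Bernoulli$(\mathrm{expit}(LP))$.

**Continuous outcome.** $y \sim N(\beta_0 + \beta_1 G,\ \sigma^2)$ with a
configurable trait SD; no subject effect (the residual SD already carries
all unexplained variation).

**Inference.** Intercept + genotype GLM (logistic or ordinary least
squares), Wald $z = \hat\beta_1 / \mathrm{SE}$, two-sided p-value, detection
when $p < \alpha$. The SE comes from the observed information at the MLE; no
robust variants. Fits are declared non-converged when the design is
rank-deficient (e.g. a cohort with no carriers at very low MAF), estimates
are non-finite, or the slope SE exceeds 100 (complete separation). A
non-converged fit is *never* a detection and is *never* resampled — at
MAF 0.008 a noticeable fraction of small-n replicates has no carriers, and
replacing them would bias power upward.

## Tunable parameters and their defaults

| parameter | default | units / scale | why |
|---|---|---|---|
| `prevalence` | 0.1 | probability | a typical common-disease candidate-gene setting; sets $\beta_0$ |
| `baseline_or` | 10 | odds ratio, 95th vs 5th risk percentile | the reference heterogeneity magnitude used throughout the binary analyses |
| `trait_sd` | 1 | outcome SD | continuous effects are then read in SD units |
| `alpha` | 0.05 | two-sided | association-study convention for a single candidate SNP |
| `target_power` | 0.80 | probability | the standard design target |
| `reps` | 1000 | replicates | Monte-Carlo SE of a power estimate ≤ 1.6 points |
| search `reps_per_step` | 500 | replicates | MC SE ≤ 2.2 points per evaluation; keeps a full search under a minute |
| effect grids | OR 1.1–1.8 / 0.1–0.8 SD | eight values | modest candidate-gene effects; the exact published values are not printed, so these are configurable stand-ins |
| fixed n for power comparisons | 3000 | individuals | places the MAF-0.1, OR-1.5 binary design mid-curve (~0.84 power), so both the power loss and its MAF trend are visible; chosen from the asymptotic power curve before any test was run |

The effect size is defined **per unit of the TRUE-model coding**: under
dominant truth it is the full carrier effect, shared by heterozygotes and
homozygotes. The additive analysis arm therefore reports a per-allele
coefficient; we deliberately do not rescale it, because the whole point is
what an analyst who (wrongly) believes the model is additive would report.

## The paired misspecification design

`run_misspec_scenario()` generates each replicate cohort **once** under the
dominant truth and fits it **twice** — carrier coding and allele-count
coding. The misspecification is a recoding, not a regeneration, so the two
arms are compared on identical data and arm differences carry no
between-cohort Monte-Carlo noise. The same idea extends to the sample-size
searches: each power evaluation keys its RNG stream on (scenario seed, n),
so whenever the two arms' searches evaluate the same n they reuse identical
cohorts. This common-random-numbers pairing is what makes the sample-size
inflation ratio $n_{misspec}/n_{true}$ — whose true value is only 1.004 at
MAF 0.008 and 1.056 at MAF 0.1 for a continuous outcome (closed form
$(2-p)/(2(1-p))$, from the least-squares projection of the carrier
indicator on the allele count) — resolvable at all at desk-scale replicate
counts.

Two closed forms anchor the continuous-outcome tests as independent oracles:
the additive slope attenuates to $\beta_1 (1 - \text{MAF})$
(since $\mathrm{Cov}(D, A) / \mathrm{Var}(A) = 1 - p$ under HWE), and
two-group Wald power is
$\Phi\!\big(|\beta_1| \sqrt{n f (1-f)} / \sigma - z_{1-\alpha/2}\big)$ with
carrier fraction $f = 1 - (1-p)^2$.

**Shrinkage** is reported as $1 - \overline{\hat\beta} / \beta_{true}$ on
the coefficient (log-OR) scale, over converged replicates. For binary
outcomes with heterogeneity, even the true-coding arm shows positive
shrinkage: the subject effect is unmodelled, so the fitted (marginal) OR is
attenuated relative to the conditional OR — logistic non-collapsibility,
not an estimation defect. The "expected" value reported next to the
estimates in effect sweeps is the configured *conditional* OR; we keep that
convention (rather than the marginal OR) because it is the quantity a study
designer specifies, and the attenuation is itself one of the phenomena the
analysis reports.

## Numerical choices in the sample-size search

The power curve in n is monotone but observed with noise, so the search is
deliberately simple and bounded: double n from `n_min = 10` until the
estimated power reaches the target, then bisect, stopping when the bracket
is narrower than 1% of its upper end (at least 1). The returned
`n_required` is the smallest *evaluated* n whose power is at or above
`target - 1 MC SE`; the search trace of every (n, power) evaluation is kept
in the result for audit. Ties resolve to the smaller n; searches error out
for null effects ("target power unreachable") and when the bracket exceeds
`n_cap = 1e7`. Because each evaluation's RNG is keyed on (seed, n), the
whole search is reproducible and independent of evaluation order.

The acceptance-level check on the inflation-ratio trend allows a 2%
decrease between consecutive MAFs: with 500 replicates per evaluation a
single search resolves n to roughly ±4%, and even with paired arms the
0.9% true gap between MAF 0.008 and 0.025 sits at the resolution limit;
the end-to-end increase from MAF 0.008 to 0.1 is asserted strictly.

## What the tests establish — and what they do not

The suite verifies the machinery against independent oracles (closed-form
2×2 log odds ratio, normal-equations OLS, analytic Wald power, the
$1-\text{MAF}$ attenuation factor), calibrates the type-I error at the
nominal α in all four outcome/coding combinations, and reproduces the
qualitative claims of the misspecification analysis: the true-model arm
needs fewer samples, achieves more power, and shrinks less, with the gap
widening as MAF grows. All of this holds in the simulated HWE world with a
single causal SNP and no covariates. The package says nothing about
recessive truths, about the reverse error (additive truth analysed as
dominant), or about how the error interacts with confounding or
gene–environment terms — those are outside its scope by design.

## Known limitations

* Exact published table values for the sweeps are not reproduced (the
  original replicate counts and fixed-n settings are unprinted);
  reduced-replicate analogues with stated defaults are produced instead.
* The Wald test is the only test offered; model-robust (MAX-type) tests
  that mitigate the misspecification are referenced context, not
  implemented.
* At MAF below ~0.005 with small n, most replicates are monomorphic and
  power estimates mostly measure the non-detection convention rather than
  the test.
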