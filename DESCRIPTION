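Package: snpmisspec
Title: Simulation-Based Power for Single-SNP Studies under Genetic Model
    Misspecification
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo power and sample-size calculation for candidate-gene
    association studies of a single bi-allelic SNP, with binary (logistic) or
    continuous (Gaussian) outcomes, and a paired analysis of the cost of
    analysing a truly dominant variant under the conventional additive
    genotype coding: loss of empirical power, inflation of the sample size
    required for a target power, and shrinkage of the estimated effect size,
    across minor-allele-frequency and effect-size grids. Genotypes are drawn
    under Hardy-Weinberg equilibrium; binary outcomes include a normally
    distributed subject effect parameterized by a baseline odds ratio between
    the 95th and 5th population risk percentiles; association is tested by a
    large-sample Wald z test on the genotype coefficient of a generalized
    linear model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    parallel,
    jsonlite,
    yaml,
    optparse,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
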