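Package: mutacc
Title: Mutational Bias and Evolvability from Mutation-Accumulation Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of phenotype data from mutation-accumulation (MA)
    experiments with clonally propagated lines and large control populations.
    Estimates per-generation mutational bias (delta-M) for each genotype and
    trait as the slope of a weighted least-squares regression of MA-line mean
    phenotypes on generations of divergence through a fixed control-mean
    intercept, and mutational evolvability (CV_m^2) as the among-line REML
    variance component of mean-scaled data divided by the mean generations of
    divergence. Provides tie-corrected Kruskal-Wallis comparisons of the
    estimates across traits, trait types, genotypes and populations, velocity
    phenotypes computed from animal trajectory point tracks, a synthetic
    MA-experiment generator for estimator validation, and an end-to-end
    pipeline with tabular reports and summary figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
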