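# mutacc

Analysis of **mutation-accumulation (MA) experiments**: estimating how
spontaneous mutations shift trait means (mutational bias) and how much
heritable variation they inject per generation (mutational evolvability),
from phenotype assays of clonally propagated MA lines and their large
control populations.

In an MA experiment, replicate lines descend from a single ancestor through
single-offspring bottlenecks, so selection is minimized and spontaneous
mutations accumulate by drift; a large control population maintained in
parallel keeps the ancestral phenotype as a baseline. After `g` generations
of divergence, a common-garden assay measures each trait on individuals from
every MA line and from the controls. `mutacc` implements the estimators this
design calls for, a synthetic-experiment generator to validate them, and
velocity phenotyping from trajectory point tracks for behavioral traits. The
default design mirrors a *Daphnia magna* experiment: 2 populations × 3
genotypes, 5 MA lines per genotype diverged for ~19–25 generations, 5
assayed individuals per MA line and 15 controls, and six traits (age at
maturity, egg number, body size, and the maximum, mean and SD of swimming
velocity).

## The estimators

**Mutational bias.** For one genotype and trait, with MA-line means `z_M,i`,
per-line generations `g_i`, and control mean `z_0`, the per-generation
change in the mean is the slope of the weighted least-squares regression of
`z_M` on `g` through a fixed intercept at `z_0`:

    R_m = Σ w_i g_i (z_M,i − z_0) / Σ w_i g_i²,   w_i = 1 / Var(z_M,i)

with weights the inverse sampling variances `s_i²/n_i`. The mutational bias
is the mean-scaled slope `ΔM = R_m / z_0`, the proportional change per
generation, comparable across traits and genotypes. Its standard error
combines the weighted residual mean square with the sampling error of the
estimated control mean propagated through the fixed intercept (which the
nearly constant `g_i` would otherwise funnel straight into the slope), and
the t-test of `R_m = 0` uses Welch–Satterthwaite effective degrees of
freedom.

**Mutational evolvability.** Raw MA observations are divided by the grand
mean of the MA-line means (so variances become squared coefficients of
variation), and a one-way random-effects model is fit by REML, partitioning
the scaled variance into among-line (`V_g`) and within-line (`V_e`)
components. The per-generation input of mean-standardized mutational
variance is

    CV_m² = V_g / ḡ

with `ḡ` the mean generations of divergence across the genotype's lines.
Significance of `V_g` comes from a permutation test (shuffling line labels)
or a 50:50 mixture restricted likelihood-ratio test.

**Hierarchy comparisons.** Tie-corrected Kruskal–Wallis tests compare the
per-genotype-trait `ΔM` estimates across traits and trait types (on `|ΔM|`,
the magnitude of change) and across genotypes and populations (signed `ΔM`,
magnitude and direction), with an exact permutation p available for small
pooled samples.

## Worked example

```r
library(mutacc)

# a synthetic experiment at the default 6-genotype, 36-cell design
records <- simulate_experiment(default_sim_config(), seed = 1)
report  <- run_ma_pipeline(records, ma_config(n_null = 200, seed = 1))

dplyr::select(report$estimates, population, genotype, trait, god, z0, delta_m, cv_m2)[1:3, ]
#> # A tibble: 3 × 7
#>   population genotype trait   god    z0  delta_m    cv_m2
#>   <chr>      <chr>    <chr> <dbl> <dbl>    <dbl>    <dbl>
#> 1 G          GA       AM     19.2 14.1  -0.00124 0
#> 2 G          GA       Egg    19.2  6.18 -0.00222 0
#> 3 G          GA       Size   19.2  3.23 -0.00251 0.000256

report$comparisons
#> # A tibble: 4 × 6
#>   grouping                   h    df        p tie_correction n_groups
#>   <chr>                  <dbl> <int>    <dbl>          <dbl>    <int>
#> 1 traits (|delta_M|)     18.3      5 0.00262               1        6
#> 2 trait type (|delta_M|) 14.7      1 0.000129              1        2
#> 3 genotypes (delta_M)    14.8      5 0.0114                1        6
#> 4 populations (delta_M)   4.49     1 0.0340                1        2
```

Each estimate row is one genotype-trait cell: `god` is its mean generations
of divergence, `z0` the control mean, `delta_m` the proportional
per-generation change (negative = trait declines under mutation
accumulation), and `cv_m2` the per-generation dimensionless mutational
variance. The comparison rows ask, top to bottom: do traits differ in
mutational magnitude, do behavioral traits out-respond non-behavioral ones,
and do genotypes/populations differ in signed response.

The package also ships published per-genotype-trait estimates from a
*D. magna* MA experiment (`dmagna_ma_estimates()`) used as a realistic input
for the hierarchy comparisons, and a thin CLI
(`inst/scripts/ma-tools.R`) with `simulate`, `delta-m`, `evolvability`,
`compare`, `run` and `plot` subcommands.

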