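---
title: "Estimating mutational bias and evolvability from MA experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutational bias and evolvability from MA experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacc)
```

## The experimental design and its model

A mutation-accumulation (MA) experiment propagates replicate lines from a
single ancestral genotype through single-offspring bottlenecks. With an
effective size near one, selection is essentially powerless within a line,
and spontaneous mutations fix by drift; the line's mean phenotype performs a
random walk away from the ancestral value. A large control population kept
in parallel — where purifying selection still removes deleterious variants —
preserves the ancestral phenotype as a baseline. After one to a few dozen
generations, a common-garden assay measures all lines and controls together.

`mutacc` models this at the line level. For a genotype-trait cell with
control mean $z_0$, line $i$ diverged for $g_i$ generations has true mean

$$z_{M,i} \sim \mathcal{N}\!\left(z_0 + g_i R_m,\; g_i V_m\right),$$

and each assayed individual adds environmental noise with variance $V_E$.
The drift term grows linearly in $g$ (Brownian accumulation), which is the
assumption that lets an among-line variance be divided by generations to
give a per-generation rate. The synthetic generator
(`simulate_experiment()`) draws from exactly this model; it is the reference
against which every estimator in the package is validated.

What the generator deliberately does *not* emulate: per-generation
genealogies, backup lines, extinction-and-restart bookkeeping (a restarted
line is just a line with small $g_i$), count-valued traits (egg counts are
simulated as reals), and any genotype-by-environment structure. Passing the
validation suite therefore demonstrates that the estimators recover the
parameters of this line-level Gaussian world at the experiment's design and
noise levels — not that real assay data meet those assumptions.

### Default design

`default_sim_config()` fixes the design at 2 populations × 3 genotypes, 5 MA
lines per genotype, 5 individuals per MA line, 15 controls per genotype, and
six traits. Generating values of $z_0$, $R_m$ and $V_m$ are taken from the
bundled published *D. magna* estimate table (`dmagna_ma_estimates()`), so
the synthetic experiment reproduces realistic effect sizes; per-line
generations are the genotype's mean generations of divergence plus
$-2,\dots,2$, spanning the published 19.2–24.8 range. The one free noise
parameter is the within-line environmental coefficient of variation,
`cv_e = 0.15` by default — a typical within-clone spread for life-history
and behavioral assays of this kind, chosen once and not revisited.

## Mutational bias

For each genotype-trait cell, each MA line contributes its mean $z_{M,i}$,
weighted by the inverse of its sampling variance $s_i^2/n_i$ (a line whose
individuals happened to be identical is caught by a variance floor,
$10^{-8} z_0^2$ by default, rather than given infinite weight). The
per-generation change in the mean is the weighted least-squares slope
through a fixed intercept at $z_0$:

$$\hat R_m = \frac{\sum_i w_i g_i (z_{M,i} - \hat z_0)}{\sum_i w_i g_i^2},
\qquad \Delta M = \frac{\hat R_m}{\hat z_0}.$$

$\Delta M$ is dimensionless per generation, so it can be compared across
traits measured in days, eggs, millimetres or pixels per second.

### Uncertainty: why the intercept error cannot be ignored

The intercept is *fixed* at the estimated control mean, but that estimate
carries sampling error. Because $g_i$ spans only 19–25 while the intercept
sits at $g = 0$, the regressor is nearly collinear with the intercept
direction: an error $\varepsilon$ in $\hat z_0$ shifts every working
response by $-\varepsilon$ and is absorbed almost entirely by the slope
(roughly as $\varepsilon/\bar g$), leaving almost no trace in the
residuals. A residual-only standard error therefore understates the slope's
uncertainty severely — in null simulations at the default design a
residual-only t-test on $L-1$ degrees of freedom rejected a true
$R_m = 0$ about 24% of the time at $\alpha = 0.05$.

`fit_rm()` therefore uses

$$\widehat{\mathrm{Var}}(\hat R_m) =
  \frac{\hat s^2}{\sum w_i g_i^2}
  + \left(\frac{\sum w_i g_i}{\sum w_i g_i^2}\right)^{\!2}
    \widehat{\mathrm{Var}}(\hat z_0),$$

with $\hat s^2$ the weighted residual mean square. The t-test of
$R_m = 0$ (`test_slope()`) uses Welch–Satterthwaite effective degrees of
freedom across the two components: the intercept term carries the control
degrees of freedom ($n_0 - 1$), and the residual term is assigned 1
effective degree of freedom rather than $L-1$. That last number deserves
explanation: with weights estimated from per-line variances on only
$n_i - 1 = 4$ degrees of freedom, the weighted standardized residuals are
$t_4$-like — they lack a fourth moment — so the residual mean square is far
more variable than a $\chi^2_{L-1}$, and its $\chi^2$-equivalent degrees of
freedom collapse. Moment matching is impossible (the required moment
diverges), so the value was fixed by null-calibration simulation at the
design this package targets (5 lines, 5 individuals per line, 15 controls):
candidate values 0.5–4 gave type-I error 0.034–0.072, with 1 yielding
0.050. With this construction the test is calibrated (verified in the test
suite) and has full power against effects of the size seen in the bundled
estimates under low assay noise.

$\hat z_0$ itself remains a plug-in constant in the *point estimates*: the
slope is still fit through the fixed intercept, and $\Delta M$ is still
$\hat R_m / \hat z_0$. Only the uncertainty propagates the control-mean
error.

## Mutational evolvability

Evolvability asks how much *mean-standardized* genetic variance mutation
injects per generation. Raw MA observations for a genotype-trait are first
divided by the grand mean of the MA-line means; variances of the scaled
data are then squared coefficients of variation. One scaling subtlety: a
literal per-line scaling (each observation by its own line's mean) forces
every scaled line mean to 1 and the among-line variance to exactly zero —
it cannot produce a nonzero evolvability, which is why the grand-mean
scalar is the default (`scaling = "grand_mean"`; the per-line variant is
available for studying within-line spread).

The scaled data are partitioned by a one-way random-effects model fit by
REML, $y_{ij} = \mu + a_i + e_{ij}$ with $a_i \sim \mathcal N(0, V_g)$
among lines and $e_{ij} \sim \mathcal N(0, V_e)$ within. The fit profiles
the REML criterion down to a 1-D search over $\lambda = V_g/V_e$ (the mean
and $V_e$ have closed forms at each $\lambda$), optimized on the log scale
and polished by a root of the analytic score; the optimum is compared
against the $\lambda = 0$ boundary, so $V_g$ is never negative and boundary
fits report exactly 0. In balanced data the interior solution coincides
with the ANOVA estimators $V_e = \mathrm{MSW}$,
$V_g = (\mathrm{MSB}-\mathrm{MSW})/n$; unbalanced fits agree with `lme4`
and with a dense grid search of the full REML criterion to at least six
digits (both checked in the test suite). Degenerate inputs (no within-line
variation at all) short-circuit to $V_e = 0$ with $V_g$ the variance of the
line means, flagged.

The evolvability is $CV_m^2 = V_g / \bar g$, the among-line component per
generation of divergence. Note that the scaled data divide by the MA grand
mean, which after $\bar g$ generations of biased mutation sits at
$z_0 + \bar g R_m$, not at $z_0$; simulation-recovery checks use that as
the generating truth (the two coincide when $R_m = 0$).

Significance of $V_g$ uses, by default, a permutation test: line labels are
shuffled across observations, $V_g$ refit, and
$p = (1 + \#\{V_g^{perm} \ge V_g^{obs}\})/(1 + n_{null})$, with
`n_null = 1000` by default in the pipeline. With 5 lines of 5 individuals,
asymptotic mixture-$\chi^2$ theory is a stretch; the permutation null is
exact under exchangeability, and its rejection rate at $\alpha = 0.05$ is
confirmed nominal by simulation. The restricted likelihood-ratio test with
the usual 50:50 $\chi^2_0\!:\!\chi^2_1$ mixture is available as
`method = "lrt"`.

## Rank-based hierarchy comparisons

The per-genotype-trait $\Delta M$ estimates are compared with
tie-corrected Kruskal–Wallis tests (`kruskal_wallis()`, delegating the
statistic to `stats::kruskal.test`): across traits and across
behavioral/non-behavioral trait types on $|\Delta M|$ (magnitude only —
direction is not comparable across traits), and across genotypes and
populations on signed $\Delta M$. The estimates enter as exchangeable
values; their differing standard errors are ignored, and no
multiple-testing correction is applied across the four levels — both
deliberate mirrors of standard practice for this design. For pooled
$N \le 12$ an exact permutation p is computed by enumerating all
reassignments of the pooled values to groups of the observed sizes. The
$\chi^2$ approximation at such small $N$ is accurate where it matters:
within 0.05 of the exact p whenever the exact p is at or below 0.15
(verified over thousands of enumerated instances), while deep in the null
region (exact p above ~0.5) it can drift by up to about 0.1 without
consequence for any decision at conventional $\alpha$.

On the bundled published estimates the four tests reproduce the expected
pattern: no significant differences among individual traits, significantly
larger $|\Delta M|$ for behavioral than non-behavioral traits, and
significant variation among genotypes and between populations, with the
German population's pooled $\Delta M$ negative and the Israel population's
positive.

```{r}
est <- dmagna_ma_estimates()
hierarchy_tests(est)
```

## Velocity phenotypes from trajectories

Behavioral traits come from tracked trajectories (e.g. MTrackJ point
exports read by `read_tracks()`). Step speeds are Euclidean displacements
over elapsed time between consecutive points; a track's phenotypes are the
maximum, mean, and sample SD of its step speeds (the SD quantifying how
erratic movement is). No smoothing or gap interpolation is applied — a
missing frame simply lengthens that step's time gap — and units follow the
input, as no pixel-to-length calibration is assumed. The statistics are
invariant to rotation and translation of the arena and scale inversely
with time units, both covered by property tests.
`simulate_tracks()` generates correlated random walks with a requested
step-speed mean and SD (Gaussian, truncated at zero — the requested
moments are realized when the SD is well below the mean) as fixtures.

## Numerical choices and tie-breaks

- REML search: `optimize()` over $\log\lambda \in [-30, 30]$, tolerance
  $10^{-12}$, polished by `uniroot` on the analytic score; boundary
  declared when the interior optimum does not beat $\lambda = 0$ by more
  than $10^{-12}$.
- Weight floor: $10^{-8} z_0^2$ (dimensionless in the trait's scale);
  floored and $n = 1$ lines are reported with warnings and logged by the
  pipeline.
- Exact KW enumeration is limited to pooled $N \le 12$ (multinomial
  coefficients stay in the tens of thousands).
- Permutation p-values use the add-one correction, so they are never
  exactly zero; all permutation draws are seeded and reproducible.
- Validation suite problem sizes: oracle agreement on 1,000 random
  regression instances; estimator recovery and test calibration on 500
  simulated experiments per check at the default design; 200–300 label
  permutations per permutation test inside calibration loops.

## Known limitations

- Estimates are per genotype-trait and univariate; no mutational
  covariances between traits, and no decomposition of $\Delta M$ into
  mutation rate and average effect.
- The residual effective-df value (1) was calibrated at the 5-line,
  5-individual design; markedly different designs (many lines, many
  individuals per line) would warrant re-deriving it, though the
  t-test only becomes conservative as the weight noise shrinks.
- The control population contributes only $\hat z_0$ and its sampling
  variance; control within-line variance is not pooled into $V_e$.
- Trait values are treated as unbounded reals throughout; strongly
  discrete or zero-inflated traits violate the Gaussian line-level model.
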