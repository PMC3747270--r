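---
title: "Power and prediction accuracy for GWAS designs: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power and prediction accuracy for GWAS designs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gwasdesign)
```

## The liability threshold model

All disease calculations in `gwasdesign` rest on a single latent-variable
model: liability $l$ is standard normal in the population, and an
individual is affected exactly when $l$ exceeds the threshold
$t = \Phi^{-1}(1-K)$, where $K$ is the population prevalence. Writing
$z = \phi(t)$, the mean liability of cases is $i = z/K$ (the selection
intensity) and of controls $-z/(1-K)$; the within-group variances after
truncation are $1 - i(i-t)$ for cases and $1 + t\,m - m^2$ (with $m$
the control mean) for controls. `liability_design(K, P)` exposes all of
these, together with the liability variance of a sample containing a
proportion $P$ of cases,

$$\mathrm{var}(l_{cc}) \;=\; P\,v_{case} + (1-P)\,v_{ctrl}
  + P(1-P)\,(i_{case}-i_{ctrl})^2 .$$

This mixture variance equals 1 exactly when $P = K$ (no ascertainment)
and grows as cases are over-sampled; at $K = 0.01$, $P = 0.5$ it is
2.329. The truncated moments are written in closed form and the test
suite verifies them against numerical integration to ten significant
digits, so every downstream formula inherits that precision.

Liability is assumed normal with a single threshold: non-normal
liability, covariate-specific thresholds, and sex-specific prevalences
are out of scope. Probabilities are validated strictly inside
$(10^{-8}, 1-10^{-8})$; more extreme prevalences would make $z/K$
numerically meaningless.

## Power: non-centrality parameters for five designs

The association test of a marker (or marker set) explaining a
proportion $q^2$ of liability variance is treated as a 1-df chi-square
test with non-centrality parameter $\lambda$; power is the upper tail
of $\chi^2_1(\lambda)$ beyond the central $1-\alpha$ quantile
(`chisq_power()`). The test is two-sided and $\alpha$ enters only
through the central quantile.

* **QT_POP** (quantitative response, population): $\lambda = N q^2$.
* **BT_POP** (binary response, population): the variance proportion is
  moved to the 0/1 observed scale, $\lambda = N q^2 z^2 / (K(1-K))$.
* **BT_CC** (binary response, ascertained case-control): the
  case-control observed-scale transformation gives
  $\lambda = N q^2 z^2 P(1-P) / (K^2(1-K)^2)$. This is the small-$q^2$
  simplification; `exact = TRUE` substitutes the
  ascertainment-inflated genetic variance (`genetic_variance_cc()`)
  for $q^2$, which matters only for large multi-locus marker sets.
* **QT_CC** (quantitative response, ascertained case-control): the
  default is the full regression form. In the ascertained sample the
  response variance is $v = \mathrm{var}(l_{cc})$, the covariance
  between response and marker score scales with $v$, and the marker
  variance itself is mildly inflated, giving
  $R^2 = q^2 v / (1 + q^2(v-1))$ and the standard regression
  non-centrality $\lambda = N R^2 / (1 - R^2)$. We chose this form as
  the default rather than the first-order approximation
  $\lambda = N q^2 v$ (available via `exact = FALSE`) because the
  residual-variance division is what the regression chi-square test
  actually measures, and at the third decimal the difference is
  already visible at $q^2 = 10^{-3}$. For the binary designs the
  plain forms are kept as defaults: there the observed-scale variance
  proportions are themselves first-order approximations, and dividing
  by $1 - R^2$ would mix conventions without improving them.
* **QB_CC** (quantitative score available in cases only): the response
  is zero for controls and the (truncated-normal) liability score for
  cases. Its variance is $P v_{case} + P(1-P) i^2$ and its covariance
  with the marker set is $q^2 [P v_{case} + P(1-P) i (i - i_{ctrl})]$,
  from which $\lambda$ follows. Numerically this design tracks BT_CC
  closely (within 0.01 of power at $K=0.01$, $P=0.5$,
  $q^2 = 10^{-3}$): scoring only the cases recovers almost nothing
  beyond their diagnosis, because the controls still contribute only
  a constant.

Monotonicity properties (power increasing in $N$, $q^2$, $\alpha$;
population binary power falling and case-control power rising as $K$
decreases; the quantitative case-control design dominating the binary
one with a gap that closes at low $K$) are asserted as property-style
tests.

## Ascertainment and variance components

Selection of cases truncates liability within each group and separates
the group means, so on the liability scale both the genetic and the
residual variance change in an ascertained sample.
`genetic_variance_cc(h2, K, P)` uses the mixture decomposition

$$\mathrm{var}(g_{cc}) = h^2\!\left[P(1 - h^2(1-v_{case}))
 + (1-P)(1 - h^2(1-v_{ctrl}))\right]
 + P(1-P)\,h^4 (i_{case}-i_{ctrl})^2,$$

i.e. within-group genetic variance shrunk by selection on liability
(the shrinkage factor follows from the bivariate-normal regression of
$g$ on $l$), plus between-group variance from the genetic means
$h^2 i_{case}$ and $h^2 i_{ctrl}$. `residual_variance_cc()` is the
mirror image in $1-h^2$. At $h^2 = 0.5$, $K = 0.01$, $P = 0.5$ the
genetic variance is 0.832 — inflated by a factor 1.66 over the
population value. The tests check these against a Monte-Carlo oracle
that simulates $(g, e)$ pairs and ascertains by thresholding, and
check that genetic, residual and (simulated) covariance components
re-assemble $\mathrm{var}(l_{cc})$.

## Expected prediction accuracy

For a predictor built from $M$ markers whose effects are estimated by
independent per-marker least squares on $N$ records, the expected
squared correlation between true and estimated genetic values has the
form $r^2 = N h^2_w / (N h^2_w + M)$, with $h^2_w$ the variance
proportion on the working scale and the residual variance approximated
by the phenotypic variance of that scale:

* quantitative trait: $h^2_w = h^2$, residual variance 1;
* disease, population 0/1 analysis: $h^2_w = h^2 z^2/(K(1-K))$,
  residual variance $K(1-K)$;
* disease, ascertained case-control 0/1 analysis:
  $h^2_w = h^2 z^2 P(1-P)/(K^2(1-K)^2)$, residual variance $P(1-P)$.

The per-marker ascertainment inflation factor is fixed at 1: when the
genetic variance is spread over a reasonable number of causal markers
(about 20 or more), each marker's share is tiny and its variance
inflation negligible. `accuracy_disease_cc()` warns, but does not
fail, below $M = 20$; an alternative per-marker inflation factor is
deliberately not implemented. The reported quantity is $r$ (with $r^2$
alongside), and at $P = K$ the case-control form reduces exactly to
the population form — the $K = P = 0.5$ corner, where all three
formulas agree, is pinned in the tests.

## The simulation engine

`sim_config()` describes the generative model the closed forms assume:
$M$ independent biallelic markers with allele frequency 0.5 (count
genotypes Binomial(2, 0.5)), equal allele effects scaled so the
genetic variance is exactly $h^2$, Gaussian residuals of variance
$1-h^2$, liability $y = g + e$, and status by thresholding at
prevalence $K$. The defaults mirror the reference scenarios: $M = 100$
markers and $N = 2000$ for power (so per-marker $q^2$ of
$10^{-4}$–$10^{-3}$ corresponds to total $h^2$ of 0.01–0.1), and
$M = N = 2000$ with $h^2 = 0.5$ for accuracy. Normal and exponential
effect-size distributions are available and are rescaled post hoc to
the same realized genetic variance; accuracy is empirically
insensitive to this choice, which the suite asserts.

Ascertainment is batched rejection sampling: population batches
(sized to overshoot the remaining quota by 10%, capped at 50 000) are
drawn until the case and control quotas $NP$ and $N(1-P)$ are filled
exactly, with a per-replicate budget of $10^7$ draws; exhausting the
budget is an explicit error naming the scenario. The expected cost is
geometric, about $NP/K$ draws per replicate, which is why
low-prevalence ascertained scenarios are the expensive ones.

The association scan uses the score statistic $N r^2$ on 1 df, where
$r$ is the genotype–response correlation. It is asymptotically
equivalent to the OLS squared $t$ statistic — the suite verifies the
exact algebraic relation $t^2 = (N-2)r^2/(1-r^2)$ against `lm()` fits
— and matches the degrees of freedom of the analytic NCP framework.
Monomorphic markers score 0 with p-value 1. A response with zero
variance is an error in `association_scan()`; `empirical_power()`
treats such replicates (possible at very low $K$ in population
sampling, where a cohort may contain no cases) as contributing no
rejections, since a constant response can declare no association.

For empirical accuracy, marker effects are estimated by marginal
regression of the 0/1 status on genotype count in the (possibly
ascertained) training cohort — the accuracy theory lives on the
observed scale, so the quantitative codings are power-only — and the
predictor is evaluated in an independent, unascertained population
sample of `N_validation` individuals generated with the same true
effects; the reported estimate is the replicate mean of
$\mathrm{cor}(g, \hat g)$ with its standard error. A population
validation sample is the default reading of "validated in the same
population"; it reproduces the reference estimates, and an ascertained
validation set can be emulated by scoring an ascertained cohort
directly.

Seeding: the master seed spawns per-replicate seeds as
$(\text{seed} + 1000003\,r) \bmod (2^{31}-1)$, so replicate $r$ is
reproducible bit-for-bit regardless of how many replicates are
requested. Identical configurations and seeds give identical
summaries.

### What the generator does and does not emulate

The simulator matches the assumptions of the analytic framework:
independent markers (no linkage disequilibrium), a single shared
allele frequency, purely additive effects, no covariates, and
per-marker (not joint or penalized) effect estimation. Agreement
between simulation and the closed forms therefore validates the
derivations, not their applicability to any particular real data set:
in real GWAS, linkage disequilibrium and the effect-size distribution
change the effective number of tests, and allele-frequency spectra
change per-marker information. Those caveats apply equally to the
formulas and to the simulation.

## Numerical choices and problem sizes

* Threshold convention: $t$ is the upper-tail threshold; cases are
  liability $> t$ (ties occur with probability zero).
* Power at the genome-wide threshold ($\alpha = 5\times10^{-8}$,
  `figure1_curves()`) is reported as a table of curves; no numeric
  reference values are attached to it.
* Analytic table cells are compared at three decimals, the precision
  at which the reference values are quoted; CLI TSV output prints six
  significant digits.
* The packaged validation runs use desk-scale replicate counts —
  20 replicates for expected-vs-observed power tables, 10–20 for
  accuracy scenarios, restricted to the cheaper prevalences
  ($K \ge 0.1$) for ascertained simulations — chosen so the full suite
  runs in about a minute while keeping empirical standard errors small
  enough for three-standard-error comparisons. `reproduce_table(...,
  full = TRUE)` restores 100 replicates, and the prevalence grids are
  arguments, so the expensive scenarios ($K \le 0.01$ ascertained,
  roughly $50\times$ the draws) can be reproduced deliberately.

## Known limitations

* The comparison column produced by the earlier case-control accuracy
  formula of the least-squares prediction literature is not
  implemented; only the population-sample form of that theory (which
  the present framework reproduces) is available.
* The mapping from prediction correlation to AUC is not provided.
* Multi-marker NCPs treat the marker set as a single variance
  component; effective-number-of-tests corrections are out of scope.
* Expected accuracies carry no analytic confidence intervals; the
  simulation summaries report empirical standard errors instead.
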