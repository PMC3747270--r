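# gwasdesign

Power and expected genomic prediction accuracy for genome-wide
association study (GWAS) designs, built on the liability threshold
model.

## The problem

Designing a GWAS means choosing a response (a binary diagnosis, a
quantitative score, or a quantitative score measured in cases only)
and a sampling scheme (a population cohort, or a case-control sample
in which cases are deliberately over-represented). Each choice changes
the power of the per-marker association test and, if the data will be
used to build a polygenic predictor, the accuracy of that predictor.
`gwasdesign` quantifies both in one framework, so the trade-offs can
be evaluated analytically before any data are collected — no allele
frequencies or effect sizes are needed, only the variance explained.

## The model

Disease liability *l* is standard normal in the population; an
individual is affected when *l* exceeds the threshold
*t* = Φ⁻¹(1 − *K*), where *K* is the prevalence. With *z* = φ(*t*),
the mean liability of cases is *i* = *z*/*K*. A marker set explaining
a proportion *q²* of liability variance yields a 1-df chi-square
association test with non-centrality parameter (NCP) λ, and
power = P(χ²₁(λ) > χ²₁,₁₋α):

| design | response / sample | NCP λ |
|---|---|---|
| QT_POP | quantitative, population | *N q²* |
| BT_POP | binary, population | *N q² z²* / (*K*(1 − *K*)) |
| BT_CC  | binary, case-control (case fraction *P*) | *N q² z² P*(1 − *P*) / (*K*²(1 − *K*)²) |
| QT_CC  | quantitative, case-control | *N R²*/(1 − *R²*), *R²* = *q²* var(*l*꜀꜀) / (1 + *q²*(var(*l*꜀꜀) − 1)) |
| QB_CC  | quantitative in cases, 0 in controls | from the mixture-response variance and covariance |

var(*l*꜀꜀) is the liability variance in the *P* : (1 − *P*)
case-control mixture, computed from the truncated-normal moments
(`liability_design()`).

Expected prediction accuracy for a predictor trained by per-marker
regression on *N* records and *M* markers follows
*r²* = *N h²*𝓌 / (*N h²*𝓌 + *M*), where *h²*𝓌 is the variance
proportion on the working scale: *h²* itself for a quantitative trait,
the observed-scale transformation *h² z²*/(*K*(1 − *K*)) for a disease
analysed as 0/1 in a population sample, and the case-control
transformation *h² z² P*(1 − *P*)/(*K*²(1 − *K*)²) under
ascertainment. A simulation engine (`sim_config()`,
`empirical_power()`, `empirical_accuracy()`) validates every closed
form.

## Worked example

```r
library(gwasdesign)

liability_design(K = 0.01, P = 0.5)
#> Liability threshold design
#>   prevalence K = 0.01, case proportion P = 0.5
#>   threshold t = 2.32635, density z = 0.02665
#>   mean liability: cases 2.66521, controls -0.02692
#>   liability variance: cases 0.09685, controls 0.93665
#>   case-control mixture liability variance = 2.32865
```

For a 1% -prevalence disease, a 50/50 case-control sample stretches
the liability variance from 1 to 2.33 — the geometric reason
ascertained designs gain power.

```r
gwas_power(c("BT_POP", "BT_CC", "QT_CC"), N = 2000, q2 = 0.001,
           K = 0.01, P = 0.5)
#>   design    K   P    N    q2 alpha       ncp      power
#> 1 BT_POP 0.01 0.5 2000 0.001  0.05 0.1435024 0.06659561
#> 2  BT_CC 0.01 0.5 2000 0.001  0.05 3.6237970 0.47759267
#> 3  QT_CC 0.01 0.5 2000 0.001  0.05 4.6619543 0.57896272
```

With 2000 individuals and a marker explaining 0.1% of liability
variance, a population sample of a 1%-prevalence disease is nearly
powerless (6.7%), a 50/50 case-control sample reaches 48% power, and
recording a quantitative liability-scale score on the same
case-control sample lifts power to 58%.

```r
gwas_accuracy("cc", N = 2000, M = 2000, h2 = 0.5, K = c(0.01, 0.1),
              P = 0.5)
#>   method    N    M  h2    K   P         r        r2
#> 1     cc 2000 2000 0.5 0.01 0.5 0.6894397 0.4753271
#> 2     cc 2000 2000 0.5 0.10 0.5 0.5676032 0.3221734
```

A predictor trained on 2000 ascertained individuals with 2000 markers
jointly explaining half the liability variance is expected to
correlate 0.69 with true genetic values at *K* = 0.01 — ascertainment
helps more, the rarer the disease. Simulation confirms the closed
forms:

```r
cfg <- sim_config(M = 100, N = 2000, h2 = 0.1, K = 0.1, P = 0.5,
                  design = "BT", ascertained = TRUE,
                  n_replicates = 20, seed = 42)
empirical_power(cfg)
#> Empirical power: 0.2905 (SE 0.0102, replicate-level SE 0.0095) over 20 replicates, seed 42
```

against the analytic 0.281 for that scenario.

## Command line

A thin CLI wraps the same functions (see `inst/cli/gwasdesign`):

```sh
Rscript inst/cli/gwasdesign power --design BT_CC --K 0.01 --P 0.5 --N 2000 --q2 0.001
Rscript inst/cli/gwasdesign accuracy --method cc --N 2000 --M 2000 --h2 0.5 --K 0.001
Rscript inst/cli/gwasdesign reproduce --table table2 --reps 20 --seed 1 --out table2.tsv
```

Subcommands accept a YAML config file (`--config`, one section per
subcommand; flags override the file) and emit TSV or JSON.

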