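# gapsurv

Integrated analysis of ordered cancer-progression events — loco-regional
relapse, progression, death — as **dependent gap times** in two-arm
trials.

Conventional trial reporting treats loco-regional control (LRC),
progression-free survival (PFS) and overall survival (OS) as separate
endpoints. `gapsurv` keeps those per-endpoint analyses (Kaplan–Meier
curves and Cox proportional-hazards models) but adds the piece they
discard: with event times `T1 ≤ T2 ≤ T3` (days from registration), the gap
times

```
G1 = T1,   Gj = Tj − T(j−1)
```

are modelled jointly —

* a Bayesian **log-normal AFT model** per gap,
  `log G = μ + β·Arm + ε`, `ε ~ N(0, σ²)`, by conjugate Gibbs sampling;
* an arm-stratified **dependency regression** of the
  progression-to-death gap on the relapse-to-progression gap,
  `G3 = β0a + β1a·G2 + e` within arm `a`, with the posterior of the slope
  contrast `β11 − β10` as the arm's effect on the dependency, and
  posterior-predictive **next-gap prediction**;
* a **combined arm signal**: the AFT arm effect on the earlier gap plus
  the slope contrast, draw-wise;
* **Cox PH per endpoint** (`λ(t|Z) = λ0(t)·exp(β1·Arm + β2·Age +
  β3·Gender)`) by Newton–Raphson maximum partial likelihood *and*
  random-walk Metropolis posterior sampling, with a Kolmogorov-type
  (Lin–Wei–Ying) supremum test of proportional hazards;
* shared metrics: AIC, DIC with effective parameter count pD, HPD
  intervals, split-R̂;
* a **synthetic two-arm trial generator** whose defaults emulate a
  74-patient head-and-neck-cancer cohort (43 vs 31), so the whole
  pipeline is runnable and testable without any external data.

It is aimed at biostatisticians analysing multi-event oncology trials who
want treatment inference that uses the ordering of events, not just each
endpoint marginally.

## Worked example

```r
library(gapsurv)

config <- analysis_config(
  sim_params = synthetic_params(seed = 1L),     # 43 + 31 subjects
  mcmc = mcmc_settings(n_chains = 2L, n_iter = 6000L, burn_in = 2000L,
                       seed = 1L))
bundle <- run_strategy(config)
render_tables(bundle)$aft_table
```

```
 Response Parameter Posterior Mean (SD)       95% HPD    DIC   pD
      PFS Intercept         5.36 (0.13)  (5.10, 5.60) 980.35 3.01
                Arm         0.03 (0.20) (-0.36, 0.41)
              Scale         0.84 (0.07)  (0.70, 0.98)
       OS Intercept         4.57 (0.15)  (4.27, 4.85) 901.99 2.97
                Arm         0.28 (0.23) (-0.16, 0.75)
              Scale         0.97 (0.08)  (0.82, 1.14)
```

The `PFS` rows model the relapse-to-progression gap, the `OS` rows the
progression-to-death gap, both on the log-day scale: e.g. a typical
relapse-to-progression duration of `exp(5.36) ≈ 213` days in the
reference arm, multiplied by `exp(0.03) ≈ 1.03` in the experimental arm
(no clear AFT arm effect here — its HPD spans 0). `Scale` is the residual
SD of the log gap. The generative truth behind this seed was
μ = 5.3, β = 0.1, σ = 0.8.

```r
bundle$difference
#> Slope difference (arm 1 - arm 0): mean 0.095 (SD 0.036), 95% HPD (0.023, 0.163)
#> P(difference > 0) = 0.995
bundle$combined
#> Combined arm inference (AFT effect + dependency-slope difference)
#>                   mean    sd hpd_lower hpd_upper
#> aft_arm_effect   0.028 0.201    -0.365     0.414
#> slope_difference 0.095 0.036     0.023     0.163
#> combined         0.123 0.203    -0.286     0.497
```

The dependency route *does* separate the arms: each extra day of
relapse-to-progression time adds about 0.095 more days of
progression-to-death time in the experimental arm than in the reference
arm (true contrast 0.45 − 0.35 = 0.10), with posterior probability 0.995
of being positive — exactly the kind of effect the marginal AFT model
missed. `render_tables(bundle)$cox_table` gives the per-endpoint Cox
summary (Arm/Age/Gender, Bayesian and MLE columns), and
`predict_next_gap(g, fit)` turns an observed relapse-to-progression gap
into a predictive interval for the remaining survival.

A thin command-line wrapper covers the same flow:

```sh
Rscript inst/cli/gapsurv.R simulate --out cohort.csv --seed 1
Rscript inst/cli/gapsurv.R cox --input cohort.csv --endpoint lrc
Rscript inst/cli/gapsurv.R run --out-dir results/
```

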