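# instarhmm

Hidden Markov models for stage-structured juvenile insect demography from
multi-state mark–recapture data.

## What problem this solves

Caterpillar cohorts are surveyed by revisiting host plants every few days
and recording, for each marked individual, what was seen: a live stage
(egg `E`, instars `L1`–`L5`, pupa `P`), a fresh corpse (`D1`–`D5`), or
nothing (`NS`). Detection is imperfect and stage-dependent, eggs and pupae
are nearly invisible, corpses disappear within days, and survivors leave
the observable population by pupating. Naively read, such data confound
mortality, missed detections, and emigration to the pupal stage.

`instarhmm` treats the encounter history of each individual as the output
of a hidden Markov model. The latent state lives in a 15-state space —
seven live stages, seven transient "newly dead" corpse classes, one
absorbing dead state — with a column-stochastic one-step kernel

```
PX = | J  Z |      J[j,i] = phi_i * psi[j,i]   (survive, then grow)
     | M  U |      M: dying mass 1 - phi_i;  Z = 0;  U: corpse -> dead
```

and an observation kernel `PO` with stage-specific detection of live
individuals (`p_live`) and corpses (`p_dead`). Survival uses a logit link
and growth a multinomial logit, each constant or linear in survey date,
conspecific density (summed body lengths per plant), or 3-day mean
temperature. Egg hatching and pupation probabilities carry informative
beta priors because the field data barely observe them. The marginal
likelihood is computed exactly by the forward algorithm (no latent-state
sampling), models are fit by blocked adaptive random-walk Metropolis, and
candidate covariate structures (a 3 × 2 × 3 = 18-model grid) are ranked by
AICc computed from the mean posterior deviance.

A synthetic-cohort generator with retained latent truth reproduces the
survey design (14 plots on a staggered 3-day rotation, 9 occasions, an
oviposition pulse, a warming trend, and an 11%-per-day log-linear increase
in per-capita predation) and backs the package's parameter-recovery and
model-selection tests. For the scientific details and every modelling
convention, see the methods vignette
(`vignettes/cohort-hmm-methods.Rmd`).

## Worked example

```r
library(instarhmm)

cohort <- simulate_cohort(cohort_config(n_individuals = 200,
                                        predation_slope = 0, seed = 42))
cohort
#> synthetic cohort: 175 detected individuals, 630 detections over 9 occasions x 14 plots

head(cohort$encounters, 5)
#>   individual_id plot_id plant_id occasion day category length_mm
#> 1       ind0001       8        5        1   1       NS        NA
#> 2       ind0001       8        5        2   4       NS        NA
#> 3       ind0001       8        5        3   7       L1      4.68
#> 4       ind0001       8        5        4  10       L1      4.08
#> 5       ind0001       8        5        5  13       L2      6.33

priors <- matched_priors(cohort$config$params, strength = 20)
fit <- fit_hmm(cohort$encounters, cohort$config$structure, priors,
               mcmc_settings(chains = 3, burn_in = 1000, samples = 1000,
                             seed = 7),
               death_partition = "stay")
fit
#> Juvenile cohort hidden Markov model (Bayesian fit)
#> model structure: survival ~ constant (early_grouped), growth ~ constant
#>   175 encounter histories, 9 occasions; K = 23 parameters
#>   3 chains x 1000 retained draws (burn-in 1000)
#>   mean posterior deviance: 1608.28
#>   block acceptance rates: survival 0.31, growth 0.29, p_live 0.31,
#>   p_dead 0.28, informative 0.32

summary(fit)[c(2, 11, 22, 23), ]
#>    parameter   mean     sd  lower  upper   psrf
#>    b0[early] 2.3212 0.1816 1.9676 2.6999 1.0027
#>  p_live[egg] 0.2820 0.0909 0.1246 0.4712 1.0210
#>        hatch 0.6437 0.0536 0.5363 0.7479 1.0037
#>     pupation 0.2843 0.0760 0.1459 0.4377 1.0003
```

`b0[early]` is the shared logit-scale survival intercept of instars I1–I4:
`plogis(2.32) = 0.91` per 3-day step, bracketing the generating value 0.92.
Detection and the informative-prior parameters are reported on the
probability scale; the generating values were `p_live[egg] = 0.2`,
`hatch = 0.6`, `pupation = 0.35`, all inside their 95% intervals, with
per-parameter Gelman–Rubin statistics near 1.

The per-capita corpse-encounter trend of a cohort simulated under the
default predation schedule (a true 11% daily increase) is recovered by
Poisson regression with a population-at-risk offset:

```r
fit_corpse_trend(simulate_cohort(cohort_config(seed = 42)))
#> Per-capita corpse-encounter trend (Poisson, log-abundance offset)
#>   log-rate slope: 0.13849 per day  (+14.85% per day)
```

A single cohort is noisy (replicate SD is about 3.3 percentage points);
averaging 50 replicates recovers the generating rate (see below).

Model selection over a candidate grid:

```r
sel <- select_models(cohort$encounters,
                     model_grid(c("constant", "date"), "early_grouped",
                                "constant"),
                     priors, mcmc_settings(chains = 1, burn_in = 1000,
                                           samples = 1000, seed = 2),
                     death_partition = "stay")
sel$ranking[, c("structure", "K", "aicc", "delta_aicc")]
```

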