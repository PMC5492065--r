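---
title: "Methods: a hidden Markov model for juvenile insect cohort demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hidden Markov model for juvenile insect cohort demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(instarhmm)
```

## The problem

Juvenile insects — eggs, larval instars, pupae — are hard to survey.
Detection is imperfect and stage-dependent, some stages are essentially
invisible, individuals die and their corpses disappear within days, and
survivors eventually leave the observable population by pupating.  A
repeated mark–recapture survey of a single recruitment pulse therefore
produces, for each individual, an *encounter history*: a sequence of
observed categories ("not seen", "seen alive in stage i", "corpse of stage
i") across survey occasions.  `instarhmm` estimates stage-specific
survival, growth, and detection probabilities from such histories, lets
each vital rate depend on covariates (survey date, conspecific density,
temperature), fits the resulting candidate models by MCMC, and ranks them
by AICc.

## The state process

Time advances in 3-day steps, one per survey interval.  The latent state
of an individual lives in a 15-state space: seven live stages (egg, five
instars I1–I5, pupa), the same seven stages as transient "newly dead"
classes in which a corpse can still be found for exactly one step, and one
absorbing dead state.  The one-step kernel is column stochastic,

$$
P_X \;=\; \begin{pmatrix} J & Z \\ M & U \end{pmatrix},
$$

where `J[j,i] = phi_i * psi[j,i]` combines stage-specific survival `phi_i`
with a growth kernel `psi` (conditional on survival), `M` routes the dying
mass `1 - phi_i` into newly-dead classes, `Z = 0` (the dead never revive),
and `U` moves every newly-dead class to the absorbing state with
probability one.  Every column sums to one — all fates are accounted for —
and the package enforces this to $10^{-12}$, comfortably inside double
precision.

Allowed growth moves per step are: egg → I1 (hatching); I1–I3 → one or two
stages up (early instars can molt twice in three days); I4 → I5; I5 →
pupa.  The pupa is terminal within the model: adult emergence is not
observed, so pupal survival and maturation are deliberately out of scope.

Two conventions for `M` are implemented.  Under `"growth"` (the fitting
default) the dying mass is partitioned by the same `psi`, encoding the
field convention that an individual that dies during a failed molt is
recorded as a death in the *new* stage.  Under `"stay"` all dying mass
remains in the current stage's newly-dead class.  The synthetic-data
generator defaults to `"stay"`: partitioning by `psi` would let dying eggs
surface as detectable larval corpses and would send dying pre-pupal fifth
instars into the unobservable newly-dead-pupa class, misaligning the
corpse survey with the live population at risk (see "The generator"
below).  Whichever convention is used, fits to simulated data should use
the generator's convention so model and data-generating process agree.

## The observation process

The observation kernel `PO` has the 15 categories as rows and true states
as columns.  A live stage `i` is recorded in its own category with
probability `p_live[i]` and missed otherwise; newly-dead stages likewise
with `p_dead[i]`.  There is no misclassification: the observed stage is
taken as the true stage.  Corpses of eggs and pupae are never found
(`p_dead` fixed at 0), pupae are never observed alive (`p_live[pupa] =
0`), and the absorbing dead state is unobservable.  Detection is constant
over time, as in the study design the model mirrors.

## Likelihood

The marginal likelihood of a history integrates the joint
state–observation process over all hidden paths.  Rather than sampling
latent states, `instarhmm` computes this exactly with the forward
algorithm, conditioning on the state at first detection (individuals enter
the study when first seen alive — a standard multi-state mark–recapture
convention; time of entry is not modeled).  Every subsequent occasion
multiplies the forward vector by the (possibly covariate-dependent)
transition kernel and the observation row of the recorded category; "not
seen" rows carry real information.  The forward vector is renormalized at
every step with the log scale accumulated, so 9-occasion histories with
probabilities far below double-precision underflow remain finite.  An
exhaustive path-enumeration oracle (`brute_force_loglik()`) verifies the
recursion to $10^{-12}$ in the test suite; the production path is a fused
C++ kernel that exploits the structural sparsity of `P_X` (at most six
fates per state).

Transition covariates are measured at the *source* occasion: the kernel
covering `[t, t+1)` uses covariate values at occasion `t`.

## Vital-rate models and the candidate grid

Survival uses a logit link, `phi = logistic(b0_g + b1_g x)`, with `x`
either absent (constant), the survey date, or conspecific density; the
grouping `g` is either fully stage-specific (egg, I1–I5) or pools I1–I4
("early") against I5, with the egg always its own class.  Growth for I1–I4
uses a multinomial logit with stasis as the reference category and — for
parsimony — one shared slope per stage across its destinations; the
covariate is absent, date, or the 3-day mean air temperature.  Egg
hatching and pupation probabilities are not multinomial-logit parameters:
they are nearly unobservable in the field and carry informative beta
priors (standing in for laboratory rearing data), supplied by the user via
`prior_spec()` or built from known truth via `matched_priors()`.

Covariates are z-standardized against the fitted dataset (stored for
back-transformation), which keeps the sampler geometry reasonable and the
model unit-free — the temperature series may be in any unit.  Density is
computed from *observed* plant co-occupants, the quantity a field worker
could record: the size-scaled metric sums observed body lengths (a biomass
proxy), the count metric counts them.  Hourly temperature series are
averaged over each plot's 3-day intervals; up to 10% of an interval's
hours may be missing (mean over available hours), more is a hard error
since a sparse record aliases the diurnal cycle.  The linear-in-covariate
forms are deliberate: nonlinear thermal performance curves and
developmental time delays are out of scope.

The default candidate grid crosses 3 survival forms × 2 groupings × 3
growth forms = 18 structures (`model_grid()`), with detection always
stage-dependent and constant.  Density candidates use the size-scaled
metric.

## Priors, sampler, and diagnostics

Coefficients get normal(0, 100) priors; detection probabilities uniform(0,
1); hatch and pupation their informative betas.  Sampling is blocked
adaptive random-walk Metropolis on an unconstrained scale (identity for
coefficients, logit with Jacobian for probabilities) in five blocks:
survival coefficients, growth coefficients, live detection, dead
detection, and the informative pair.  Proposal scales adapt toward a 0.3
acceptance rate and proposal covariances adapt to the running sample
covariance, both with a diminishing schedule frozen when burn-in ends, so
retained draws come from a valid Markov chain targeting the posterior.
The proposal is a symmetric two-component mixture — the adapted step, or
(with probability 0.1) three times it — which traverses the heavy
logit-scale tails of weakly identified detection parameters that a single
adapted step size undersamples.
Each recorded iteration performs two Metropolis sweeps over the blocks;
with the scaled-down settings used in simulation testing (2,000 burn-in,
2,000 retained, 3 chains) the single-sweep four-block variant (detection
as one block) does not reach convergence (max psrf ≈ 3) while the
five-block two-sweep sampler does (max psrf ≈ 1.02).  Default settings
mirror a study-scale run (120,000 burn-in, 10,000 retained, no thinning, 3
chains).

Chains start from overdispersed values centered on field-plausible rates
(logit-scale sd 0.8; survival near 0.85, detection near 0.7, informative
parameters drawn from their priors).  Drawing starts from the sd-100
coefficient priors instead would initialize chains at numerically
degenerate probabilities (logistic of ±100) and make any practical burn-in
useless.

Convergence is monitored with per-parameter Gelman–Rubin statistics
(`psrf = sqrt(((n-1)/n W + B/n)/W)`; parameters with zero within-chain
variance are flagged, not fabricated), the Brooks–Gelman multivariate psrf
from the largest eigenvalue of $W^{-1}B/n$, and a multivariate effective
sample size `mESS = n (det Λ / det Σ)^{1/p}` with `Σ` estimated by batch
means (batch size `floor(sqrt(n))`, per-chain estimates summed).  These
are the standard definitions; where the literature admits variants (psrf
with or without the `(m+1)/m` inflation, ESS batch size) the plain forms
above are used and tested against an independent implementation.

## Model selection

Candidate structures are ranked by AICc with the *mean posterior deviance*
in place of the maximized-likelihood deviance — DIC is deliberately not
offered because its effective-parameter count can go negative for models
of this kind.  `K` counts all sampled parameters, including the two
informative-prior parameters (a switch excludes them), and the
small-sample `n` is the number of encounter histories; both conventions
are documented rather than claimed, since the choice is genuinely open.
Ties are broken by smaller `K`, then lexicographic structure label, so
rankings are order-invariant.

## The generator

`simulate_cohort()` emulates the survey the model assumes: 14 plots on a
3-day rotation (9 occasions each, one third of the plots surveyed per
day), arrival days drawn from a Gaussian oviposition pulse (peak day 8, sd
5), individuals placed uniformly on plots and plants, latent states
propagated by the true kernels, observations drawn from `PO`, and body
lengths for detected instars drawn around stage means 4.1, 6.4, 9.4,
13.3, 19.9 mm (sd 0.5) — the reported field means.  The hourly temperature
series rises 20 °F over 30 days with a diurnal sinusoid (amplitude 8) and
noise (sd 2).

Mortality carries a log-linear predation trend: per-step death
probabilities are scaled by `exp(s (day - 13))`, with default `s =
log(1.11)` — an 11% daily increase in per-capita predation risk, the
reported field value.  The mid-season reference day keeps scaled
probabilities inside (0, 1).  Setting `s = 0` yields data generated
exactly under the constant-survival structure; recovery and
model-selection simulations do this.  Baseline rates the source system
does not pin down are package conventions chosen once: 3-day survival 0.90
(egg) / 0.92 (instars), hatch 0.6, pupation 0.35, growth probabilities
declining with stage (I1: 0.55 + 0.15 advance, I4: 0.45, so later instars
take longer per stage), live detection 0.9/0.9/0.8/0.8/0.9 for I1–I5 with
0.2 for eggs, corpse detection 0.5 for instars.

Two deliberate observability rules mirror the field: corpses are
detectable for exactly one step before vanishing, and individuals enter
the *marked* sample only when first detected alive.  Because a field
worker nevertheless records every corpse encountered, the generator also
returns a `corpse_survey` table of all corpse detections (marked or not)
together with the detected live-instar count per plot survey.  The
per-capita corpse-encounter trend (`fit_corpse_trend()`) regresses those
corpse counts on the survey day by Poisson regression with the log of the
previous survey's live-instar count — the population at risk — as offset,
and reports `100 (exp(slope) - 1)` percent per day.  Fitting marked-only
corpse counts instead recovers a visibly biased trend (low early-season
egg detectability censors early corpses); the data-frame method of
`fit_corpse_trend()` does exactly that and is documented as such.

What the generator does *not* emulate: movement between plants or plots,
predator dynamics (the predation trend is imposed, not emergent),
resource depletion, misidentification, and temperature-driven development
beyond the linear link.  Passing the package's recovery tests therefore
shows internal consistency — the estimator recovers the process the model
assumes — not robustness to these violations in real data.

## Numerical choices and degenerate inputs

Column-stochasticity and simplex checks use a $10^{-12}$ tolerance.
Multinomial-logit softmaxes subtract the maximum logit, so coefficients of
any magnitude cannot overflow.  Impossible histories return `-Inf`
log-likelihood (and `+Inf` deviance) rather than an error; histories with
no detection, or that start with a corpse, are rejected with row-numbered
errors at validation.  The AICc correction refuses `n ≤ K + 1`.  A
non-finite posterior at initialization triggers up to 50 fresh draws
before failing with advice.  Chains are reproducible bit-for-bit given
`mcmc_settings(seed = )`.

## Scaled-down study sizes

Simulation-based tests use sizes chosen to exercise the claims while
staying desk-scale: parameter recovery uses 20 replicate cohorts of 300
individuals with 2,000/2,000 MCMC iterations, 3 chains, and three
Metropolis sweeps per recorded iteration; model self-selection uses 20
replicates of 150 individuals over a 4-structure grid (constant vs date
survival × constant vs date growth, early-grouped) with 1,000/1,000
iterations and a single chain; the predation-trend recovery uses 50
cohorts of 500 individuals.  These sizes are the package's own test
design; the full-scale defaults remain available through
`mcmc_settings()`.

Both simulation studies pass weakly-informative normal(0, 10) coefficient
priors instead of the sd-100 default.  Parameters the data bound only
from one side — egg survival, say, since egg corpses are invisible —
otherwise have a logit-scale plateau roughly as wide as the prior, which
no random-walk sampler can traverse inside a 2,000-iteration budget.  An
sd of 10 is still flat over probabilities between about 4e-5 and 0.99995
and diffuse relative to every generating value, so it changes nothing the
recovery test measures; the sd-100 default remains appropriate for
study-scale runs with long burn-in.
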