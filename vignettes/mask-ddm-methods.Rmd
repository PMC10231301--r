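---
title: "Modeling masked-expression emotion judgments with the drift-diffusion model"
author: "maskddm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling masked-expression emotion judgments with the drift-diffusion model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(maskddm)
```

## The scientific problem

When half of a face is covered — by a surgical-style mask over the mouth, or
(as a control) an occluder over the eyes — observers still judge emotional
expressions far better than chance, but they become both less accurate and
slower. `maskddm` provides the full inferential machinery for asking *why*:
it models each yes/no emotion judgment as a noisy evidence-accumulation
process, so that accuracy and speed deficits can be traced to a single latent
quantity, the **drift rate** — the mean rate at which perceptual evidence for
the correct judgment accrues.

The package covers the whole workflow of a masked-expression rating study:
counterbalanced task design, simulation of complete datasets from a known
generative model, pre-registered exclusions, hierarchical Bayesian estimation
of condition-specific drift rates, posterior-probability hypothesis tests,
and bootstrap mixed-effect regressions of ratings and response times. Because
the human data of such studies are not shipped here, every analysis is
exercised end-to-end on synthetic data with known ground truth; parameter
recovery, not reproduction of any particular dataset, is the standard the
test suite enforces.

## The decision model

A trial is modeled as a Wiener diffusion with unit diffusion coefficient
between two absorbing boundaries separated by $a$ (evidence units). The
process starts at relative position $z \in (0,1)$ and drifts at rate $v$
(evidence/s). Under **accuracy coding** the upper boundary is the correct
response, so $v > 0$ means evidence flows toward the correct judgment — for a
congruent trial (expression matches the rated emotion) a correct "yes", for
an incongruent trial a correct "no". Observed response time is the boundary
passage time plus a non-decision time $t$ (encoding and motor processes).
The full model adds inter-trial variabilities: drift $\sim N(v, sv^2)$,
start point uniform on $z \pm sz/2$, non-decision time uniform on
$t \pm st/2$.

The likelihood kernel is the Wiener first-passage-time (WFPT) density,
implemented in compiled code as the classical two-regime series: a
small-time expansion in image terms and a large-time sine series, with the
published term-count switching rule controlled by a truncation tolerance
(`rel_tol`, default `1e-6`). Drift variability is marginalised analytically
(normal mixing multiplies the zero-drift kernel by a closed-form factor);
$sz$ and $st$ are marginalised by Gauss-Legendre quadrature, with adaptive
node doubling in `integrate_variabilities()`. Two closed forms anchor all
validation: the upper-boundary absorption probability
$(1-e^{-2vaz})/(1-e^{-2va})$ and, for the driftless process, the mean
passage time $az \cdot a(1-z)$.

Times are seconds internally; trial tables carry `rt_ms` and are converted
once at the model boundary.

## Task design

Six blocks of stimuli are fully counterbalanced: each actor appears in every
block with exactly one expression and all three mask conditions (lower-face
mask, upper-face mask, none), each expression is carried by `n_actors/6`
actors per block, and every (actor, expression, mask) triple occurs exactly
once across the block set. The construction is a balanced Latin square over
actor groups: actors are dealt round-robin into six groups within
gender-(and, when given, ethnicity-)strata, and a random base permutation of
expressions is rotated across blocks. Round-robin dealing guarantees group
sizes are exact and stratum composition is balanced to within one actor;
when a stratum does not divide evenly by six the generator reports the
approximation in a logged message rather than failing, because real stimulus
sets are rarely perfectly factorial.

Per participant, the pairing of rating-emotion to block is randomized
jointly and independently (the alternative — independent randomization of
block order and rating order — is observationally equivalent for the
analyses here, since each round is a (block, emotion) pair either way). The
hand assigned to "yes" is drawn once per participant.

## The synthetic-data generator

`ground_truth()` fixes the generative structure the inference must recover:
a drift coefficient for each (emotion x mask) cell of congruent trials, a
single drift for correct rejection on incongruent trials, a participant
random intercept on drift, shared $a, z, t, sv, sz, st$, a fast-guess
contamination rate, and an attention-failure rate. Defaults encode the
qualitative structure such studies report: unmasked drift near 1.8
evidence-units/s, boundary separation 1.77, non-decision time 0.35 s,
deficits of roughly 0.4-0.7 units for mouth-diagnostic emotions (disgust,
happiness, sadness, surprise) under lower masks and for eye-diagnostic
emotions (anger, fear) under upper masks, participant intercept SD 0.3,
2% fast-guess contamination, and attention-failure rates matching the two
study profiles (24% and 9%).

Choices and RTs are simulated by small-step Euler-Maruyama integration
(default `dt = 1e-4` s) with the Broadie-Glasserman-Kou continuity
correction — each boundary is shifted inward by $0.5826\sqrt{dt}$ — which
removes the leading-order bias from monitoring a continuous barrier at
discrete steps; without it the simulated mean passage time runs about 1%
long at this step size. Paths exceeding a time cap are resampled and
counted. The simulator uses its own deterministic RNG stream (splitmix64
seeding, xoroshiro128+, ziggurat normals), so a dataset is a pure function
of its integer seed regardless of R's RNG state.

What the generator does *not* emulate: perceptual properties of real face
stimuli, sequential effects, learning or fatigue across rounds, and
emotion-specific non-decision times. Passing tests therefore demonstrate
that the machinery is correct and well calibrated on data satisfying the
model's assumptions — not that real data satisfy them.

## Exclusions

The pre-registered cascade: participants failing attention checks are
removed first; then trials faster than 100 ms; then trials above the
empirical top-0.5% threshold, computed over all remaining trials of retained
participants (one threshold per dataset). The threshold uses the inverse
empirical-CDF (type-1) quantile — an observed value — with strictly-greater
removal and ties retained, so at most 0.5% of trials are ever trimmed and
tiny inputs are not over-trimmed, which interpolation-based definitions do.
Ordering (fast rule before quantile rule) is a package decision and is
recorded in the `exclusion_report`; only the fast rule is idempotent, since
the quantile is recomputed on whatever it is given.

## Hierarchical inference

The estimation model uses cell-means coding: one drift coefficient per mask
condition (contrasts are computed on draws, matching per-condition
reporting), a participant random intercept on drift with a half-normal(0,1)
group-SD prior, and shared $a, z, t, sv$ estimated once across mask
conditions ("averaging over mask conditions" is read as shared-parameter
estimation; post-hoc averaging of per-condition fits is the recorded
alternative). A follow-up variant indexes boundary separation by mask while
retaining drift-by-mask, mirroring the logic of checking whether apparent
drift effects are boundary effects in disguise. Priors are weakly
informative and config-exposed: normal(0, 2^2) drift coefficients,
truncated normals on $a$ (1.5, 1), $z$ (0.5, 0.25) and $t$ (0.3, 0.25),
half-normal(0, 2) on $sv$. $sz$ and $st$ are fixed (default 0) rather than
estimated: uniform-range variabilities are weakly identified at these trial
counts and their quadrature triples the likelihood cost.

Sampling is single-chain adaptive Metropolis-within-Gibbs over blocks —
drift coefficients, participant intercepts, intercept SD, shared
parameters — with positive parameters proposed on the log scale and the
start point on the logit scale (Jacobians included). Proposal scales start
at roughly the inverse root information and are tuned toward 20-50%
acceptance in batches of 20 during burn-in only, so retained draws come
from a fixed kernel. Initialisation uses moment-based (EZ-style) estimates
from accuracy and RT mean/variance, which places the chain near the
posterior mode and makes the protocol's short 200-draw burn-in workable.
The reporting protocol is 5000 draws with the first 200 discarded (4800
retained); a multi-chain mode exists for diagnostics. Split-half $\hat R$
and autocorrelation-based effective sample sizes are attached to every fit.

Hypothesis tests are posterior tail fractions: `posterior_prob()` evaluates
contrasts such as `"v_lower > v_none"` as the fraction of retained draws
satisfying the inequality, with exact ties contributing 1/2 (so
$P(A>B) + P(A<B) = 1$). `compare_fits()` pairs draws across two independent
fits to estimate cross-study contrasts such as
$P(\text{lower}_2 - \text{none}_2 > \text{lower}_1 - \text{none}_1)$,
resampling with replacement (seeded) when draw counts differ.

## Behavioral regressions

Emotion ratings are analyzed with two-tailed mixed binomial logistic models
(participant random intercepts, Laplace approximation via `lme4::glmer`);
without clustering the fit reduces to ordinary logistic regression, whose
coefficient on a 2x2 table is the closed-form log odds ratio — the exact
oracle the tests use. Log-transformed RTs are analyzed with linear mixed
models on the mask-by-accuracy interaction, reported as the interaction plus
the two simple effects ("Correct: lower > none", "Incorrect: lower > none");
the flipped (negated) log RT exists only in the plotting layer. Confidence
intervals come from a percentile cluster bootstrap with participants — the
random-effect unit — as the resampling unit, 1000 iterations by default;
more than 5% failed refits aborts with the failure log. Chance-level
performance is tested per condition via the intercept of a
random-intercept-only logistic model against logit(0.5) = 0.

For coverage calibration the bootstrap wraps the population-averaged
(marginal) logistic fit and is scored against the marginal log-odds contrast
obtained by Gauss-Hermite integration over the intercept distribution:
logistic non-collapsibility means the conditional (subject-specific)
coefficient is the wrong target for a marginal estimator, and the cluster
bootstrap is precisely the device that makes the marginal fit
cluster-robust.

The false-positive cascade mirrors the conditional reporting style of such
studies: for each of the 30 incongruent pairings the rating model always
runs; the RT model runs only where a mask influenced ratings (two-tailed
p < 0.05 on a vs-none contrast, uncorrected by default, with a
Benjamini-Hochberg option exposed); the drift model runs only where the RT
effect is also significant. The per-pairing decision trail is returned.

## Pipeline and reproducibility

`run_pipeline()` executes design, simulation, exclusions, regressions,
drift-rate estimation and reporting from one configuration. A single
top-level seed fans out to per-stage seeds through a documented 32-bit
mixing function (`derive_seed()`), so one integer reproduces a run
byte-for-byte; every emitted summary number is recomputable from the
persisted draw and trial tables, and `validate_tables()` re-checks the
conservation invariants (exclusion counts, 6/30 pairing counts, draw
counts, summary-vs-draws agreement) from the files alone. The configuration
accepts an `sa` field (inter-trial variability of boundary separation) for
interface completeness but leaves it inert: such a variability is
nonstandard in the diffusion literature and its intended meaning is
ambiguous, so the package declines to guess.

## Problem sizes and numerical choices

Desk-scale defaults keep the full workflow runnable in minutes while
remaining faithful in structure. The `demo` profile uses 12 actors and 24
participants with drift attenuated to 40% (accuracy ~0.7-0.8, so every
mask-by-accuracy cell stays populated for the interaction models), 600 MCMC
draws with 200 burn-in, and 50 bootstrap iterations; the `study1`/`study2`
profiles carry the published scale (36/18 actors, 300/290 recruited, 5000
draws, 1000 bootstrap iterations). Calibration suites use 40 participants
with 18 trials per mask cell — the per-emotion congruent trial count of the
smaller study — with 1200-1500 MCMC draws, which posterior-mean stability
checks show is ample for tail probabilities at the 0.05 level. Simulator
validation uses $10^5$-$10^6$ Euler-Maruyama paths at `dt = 1e-4`, binned
L1 agreement with the series density below 0.02, and density mass
conservation to $10^{-4}$.

Degenerate inputs are handled by contract: RTs at or below non-decision
time have zero density (not an error); all-constant outcomes fall back from
`glmer` to an adjusted-logit estimate in `chance_test()`; complete
separation and rank deficiency raise errors naming the offending cells;
non-finite initial log-posteriors retry with shrunken non-decision time
before failing.

## Known limitations

Inference quality is bounded by the model: no across-trial contaminant
mixture in the likelihood (outliers are handled by exclusion, as
pre-registered), no random slopes (intercepts only, as specified), no
emotion term when collapsing across emotions (an option exists), and fixed
rather than estimated $sz$/$st$. Whether emotion-specific fits should be
separate models or one joint model is left to the caller; the default fits
per-emotion models, matching per-emotion coefficient reporting, and the
joint alternative is a subset call away. The sampler is random-walk
Metropolis by design — transparent and dependency-free — and correspondingly
needs its moment-based initialisation; gradient-based samplers are out of
scope.
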