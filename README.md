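# maskddm

Drift-diffusion analysis of emotion judgments of masked faces.

When the lower or upper half of a face is covered, observers still recognize
emotional expressions above chance — but they become less accurate and
slower. `maskddm` implements the inferential machinery for studying *why*,
for researchers in perception, social cognition and computational
psychiatry who work with two-alternative forced-choice (2AFC) choice/RT
data: each yes/no emotion judgment is modeled as a Wiener diffusion between
two absorbing boundaries, so accuracy and speed deficits can be traced to
the **drift rate** *v* — the mean rate of evidence accumulation toward the
correct response.

## The model

A trial is a unit-diffusion Wiener process between boundaries separated by
*a*, started at relative position *z*, drifting at *v* (evidence/s), with
non-decision time *t* and inter-trial variabilities *sv*, *sz*, *st*
(accuracy coding: the upper boundary is the correct response). The
likelihood is the Wiener first-passage-time (WFPT) density, computed in
compiled code via the standard small-time/large-time series with analytic
marginalisation of *sv*; the closed-form upper-boundary absorption
probability

P(upper) = (1 − e^(−2vaz)) / (1 − e^(−2va))

anchors all validation. Condition-specific drift coefficients (one per mask
condition: lower, upper, none) with participant random intercepts are
estimated by adaptive Metropolis-within-Gibbs MCMC (protocol: 5000 draws,
200 burn-in), and hypotheses are tested as posterior tail fractions, e.g.
P(v_lower > v_none). Around the diffusion model sit the full study
workflow: counterbalanced block designs, a ground-truth-known study
simulator, pre-registered exclusions (attention checks, RT < 100 ms, top
0.5% trim), bootstrap mixed-effect regressions of ratings and log-RTs, and
a seeded end-to-end pipeline.

## Worked example

Simulate a 40-participant study on the smaller (18-actor) design, apply the
exclusion cascade, and estimate mask effects on drift for disgust
judgments:

```r
library(maskddm)

design   <- generate_blocks(n_actors = 18, seed = 1)     # 324 stimuli, 54/block
schedule <- schedule_rounds(sprintf("P%03d", 1:40), seed = 1)
truth    <- ground_truth(attention_fail_rate = 0.1)      # known generative model
trials   <- simulate_study(design, schedule, truth, seed = 1)  # 12,960 trials

pp <- preprocess_trials(trials)
pp$report
#> Exclusion report
#>   participants: 40 in, 2 excluded (attention), 38 retained
#>   trials: 12312 in, 219 fast (< rule), 60 slow (> 2599.5 ms), 12033 retained

cong <- pp$trials[pp$trials$congruent & pp$trials$rated_emotion == "disgust", ]
fit  <- sample_posterior(build_model(cong, ddm_model_spec()),
                         n_samples = 2000, burn_in = 200, seed = 2)
summary(fit)
#>   parameter  mean     sd ci_low ci_high rhat  ess
#> 1   v_lower 1.250 0.1846 0.9351   1.638 1.02 47.4
#> 2   v_upper 1.693 0.2316 1.2710   2.198 1.01 41.4
#> 3    v_none 2.062 0.2297 1.6319   2.558 1.02 39.0
#> 4         a 1.834 0.0810 1.6943   1.995 1.03 35.7
#> 5         z 0.512 0.0309 0.4529   0.568 1.00 50.4
#> 6        t0 0.363 0.0136 0.3368   0.386 1.01 54.6
#> 7        sv 0.293 0.2176 0.0088   0.769 1.03 30.0
#> 8      u_sd 0.356 0.1249 0.0756   0.603 1.04 16.3

posterior_prob(fit, "v_lower > v_none")
#> P(v_lower > v_none) = 0.0000
```

The generating truth for disgust was v = 1.1 (lower), 1.7 (upper), 1.8
(none): the fit recovers the ordering, every 95% credible interval covers
its true value, and the lower-mask deficit is detected —
P(v_lower > v_none) < 0.001 means essentially no posterior mass has the
lower-mask drift exceeding the unmasked drift. The shared parameters land
on their true values (a = 1.77, z = 0.5, t = 0.35 s, sv = 0.2,
intercept SD = 0.3). The companion rating analysis:

```r
fit_logistic_mixed(cong)
#> Regression contrasts (b [95% CI], z, p)
#>           term      b               CI     z      p
#>   lower > none -1.992 [-3.520, -0.464] -2.56 0.0106
#>   upper > none -1.147 [-2.785,  0.491] -1.37 0.1698
#>  lower > upper -0.845 [-1.858,  0.169] -1.63 0.1025
```

— lower-masked disgust is judged less accurately than unmasked disgust
(negative log-odds contrast), consistent with the drift result.

A complete run — design through validated report tables — is one call:

```r
run_pipeline(pipeline_config("demo", seed = 1), "runs/demo")
```

or from a shell, `Rscript inst/cli/maskddm.R run --study demo --seed 1
--out runs/demo`.

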