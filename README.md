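# pushpull

Diffusion-model analysis of approach–avoidance joystick tasks.

In an approach–avoidance task, participants push a joystick away from
themselves (avoidance) or pull it toward themselves (approach) to classify
angry and happy facial expressions, with the response mapping reversed
between blocks. Mean reaction times confound several processes; the
diffusion decision model separates them. `pushpull` provides the full
analysis chain for trial-level data from this task — and a synthetic
experiment generator so every stage can be exercised and validated without
access to raw lab data.

## What it computes

The two-boundary Wiener process accumulates evidence `dX = v·dt +
s·√dt·N(0,1)` from an unbiased start `z = a/2` until absorption at `0` or
`a`; the response time is the first-passage time plus the non-decision time
`Ter`. The EZ-diffusion method recovers the three free parameters per
participant and design cell in closed form from the proportion correct
`Pc`, the mean `MRT` and variance `VRT` of correct response times. With
`L = logit(Pc)`:

```
v   = sign(Pc − ½) · s · ( L (L Pc² − L Pc + Pc − ½) / VRT )^¼
a   = s² L / v
Ter = MRT − (a / 2v) · (1 − e^(−va/s²)) / (1 + e^(−va/s²))
```

Around this core the package provides:

- **Synthetic experiments** (`generate_design()`, `default_scenario()`,
  `generate_dataset()`): the 2 (expression) × 2 (response) × 2 (face
  gender) within × 2 (participant gender) between design — 16 practice +
  2 × 128 main trials per participant — with Wiener-process response
  times, contaminant trials, and BIS/BAS questionnaire totals.
- **Preprocessing** (`filter_rts()`, `exclude_participants()`,
  `summarize_cells()`): the standard 200–2500 ms trim, the >45 % error
  exclusion rule, and per-cell summary statistics.
- **EZ estimation** (`ez_forward()`, `ez_inverse()`, `edge_correct()`,
  `estimate_all()`): the exact forward/inverse pair plus the `1/(2n)`
  edge correction for perfect cells.
- **Bayesian inference** (`run_bayes_anova()`, `jzs_ttest_bf()`,
  `effect_size_hdi()`, `classify_bf()`): BIC-approximate Bayes factors for
  every ANOVA-style model term against a participant-random-intercept
  null, exact JZS Bayes factors for paired contrasts, standardised effect
  sizes `dz` with 95 % highest-density intervals, and Jeffreys evidence
  labels.
- **Accuracy and covariate models** (`fit_gee_binomial()`,
  `fit_exgauss_regression()`): binomial GEE with exchangeable working
  correlation and robust standard errors; ex-Gaussian response-time
  regression with 2-SD-scaled BIS/BAS covariates.
- **Model-fit assessment** (`posterior_predict()`, `fit_summary()`):
  posterior-predictive simulation from the fitted parameters and
  observed-vs-predicted median/percentile comparison per cell.
- **Orchestration** (`pipeline_config()`, `run_pipeline()`,
  `recovery_study()`): a seeded, manifest-writing pipeline from raw or
  synthetic trials to a markdown report.

Fitted objects support `tidy()` and `glance()`; result tables are tibbles
and plot via `autoplot()` / `plot_condition_means()`.

## Worked example

```r
library(pushpull)
library(dplyr)

scenario  <- default_scenario(n_participants_per_gender = 32, seed = 11)
data      <- generate_dataset(scenario)
kept      <- filter_rts(exclude_participants(data$trials)$trials)
estimates <- estimate_all(summarize_cells(kept$trials))

drift <- estimates |>
  filter(!degenerate) |>
  transmute(participant_id, participant_gender, expression,
            required_response, face_gender, value = v)

head(run_bayes_anova(drift, dv = "value"), 2)
#>   dv    term                                               bf10 label    method
#> 1 value expression                                      1.99e+7 decisive bic-approx
#> 2 value expression:required_response:participant_gender 2.16e+0 anecdotal bic-approx

f <- simple_interaction_followup(drift, "female", "value", seed = 1)
f$interaction
#>   dv    group  term                          bf10 label  method
#> 1 value female expression:required_response  16.9 strong jzs-ttest
f$contrasts
#>   contrast               dz hdi_low hdi_high  bf10 label
#> 1 angry: push - pull  0.559   0.184  0.932   10.9  strong
#> 2 happy: push - pull -0.366  -0.720 -0.00282  1.23 anecdotal
```

Reading: drift rates carry a decisive expression effect, and for female
participants the expression × response interaction is strongly supported —
drift is higher when pushing (avoiding) angry faces (`dz = 0.56`) and
higher when pulling (approaching) happy faces (`dz = −0.37` on the
push-minus-pull scale) — the approach–avoidance pattern the generator
builds in for the female group only.

The same chain runs as one call, writing CSVs, a manifest and a report:

```r
run_pipeline(pipeline_config("synthetic", scenario = scenario,
                             seed = 11, out_dir = "run1"))
```

## Documentation

The methods vignette (`vignettes/pushpull-methods.Rmd`) describes the
model, the estimator, the inference machinery, the synthetic-data
generator's assumptions, and known limitations.
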