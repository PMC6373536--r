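---
title: "Methods: diffusion-model analysis of approach-avoidance joystick data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diffusion-model analysis of approach-avoidance joystick data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, estimators and numerical choices
behind `pushpull`, in the spirit of a statistical-methods appendix. It
states no empirical claims beyond what the package's tests and the
acceptance script themselves compute.

## The task and the model

Participants classify angry and happy facial expressions by pushing or
pulling a joystick; the expression-to-response mapping reverses between
the two main blocks, so every participant provides both
avoidance-compatible (push-angry) and approach-compatible (pull-happy)
responses. Decisions are modelled as a two-boundary Wiener process:
evidence `X` starts at `z = a/2`, evolves as `dX = v dt + s sqrt(dt)
N(0,1)`, and a response is emitted when `X` reaches `a` (the response
required by the mapping) or `0` (the other response). The observed
response time adds a non-decision time `Ter` for encoding and motor
execution.

Interpretation of the three free parameters, per participant and design
cell:

| parameter | units | meaning |
|---|---|---|
| `v` (drift rate) | evidence/s | quality of evidence accumulation |
| `a` (boundary separation) | evidence units | response caution |
| `Ter` (non-decision time) | s | encoding + motor time |

The noise scale `s` is not estimable jointly with the others; it fixes
the measurement scale. We use `s = 1` throughout. Drift rates near 2 in
this convention correspond to drift rates near 0.2 in the older
`s = 0.1` convention; all parameters scale linearly (`v`, `a`
proportional to `s`; `Ter` invariant), and `ez_inverse()` threads `s`
explicitly so either convention can be requested.

The starting point is always `z = a/2` (no response bias) and no
trial-to-trial parameter variability is modelled. Two consequences
matter downstream: the probability of a correct response is
`Pc = 1/(1 + exp(-v a / s^2))`, and the decision-time distributions of
correct and error responses coincide, so moments computed from correct
trials alone characterise the full process.

## Simulating first-passage times

`simulate_rts()` integrates the process by Euler-Maruyama with step
`dt = 0.0005 s`. Plain Euler-Maruyama systematically misses
within-step boundary crossings — an effective boundary shift of about
`0.583 s sqrt(dt)` per boundary, which is large enough to push hitting
probabilities to the edge of Monte-Carlo error at 50,000 trials. We
therefore add the standard Brownian-bridge correction: conditional on a
step from `x0` to `x1` remaining inside `(0, a)`, the bridge touched the
upper boundary with probability `exp(-2 (a - x0)(a - x1) / (s^2 dt))`
(and analogously the lower), and the trial is absorbed with that
probability. With the correction, the remaining discretisation bias is
`O(dt)` and invisible at the sample sizes used anywhere in the package;
the test suite verifies hitting probabilities against the closed form
within 3 Monte-Carlo standard errors at `n = 50,000` across a parameter
grid. Trials not absorbed within `max_time = 10 s` (a practical
impossibility for task-typical parameters, where mean decision times are
a few hundred milliseconds) are censored there and resolved to the
nearer boundary. The sampler is written in C++ (Rcpp) and draws from R's
RNG, so `set.seed()` governs it.

## Preprocessing

Three rules, applied in a fixed order by `run_pipeline()`:

1. **Participant exclusion first, on untrimmed data**: participants with
   a main-block error proportion strictly above 45% are removed. The
   alternative order (exclude after trimming) is defensible; we fix this
   one and document it, since the choice is ambiguous in common
   practice and the two orders differ only for participants straddling
   the threshold.
2. **Response-time trimming**: trials with RT < 200 ms or > 2500 ms are
   removed (strict inequalities — 200 and 2500 survive). The removed
   proportion is reported over main-block trials.
3. **Practice trials never enter any analysis.**

`summarize_cells()` then reduces trials to per-participant cell
statistics: trial counts, proportion correct, and mean/variance/median
of correct RTs. Mean and variance are converted to seconds (the EZ
equations' units; variances in ms² would change `v` by a factor of
`1000^(1/4)`); the median stays in ms for reporting. Variances use the
`n − 1` denominator.

## EZ estimation and edge cases

`ez_forward()`/`ez_inverse()` implement the closed-form map between
`(v, a, Ter)` and `(Pc, MRT, VRT)` and its exact algebraic inverse; the
test suite demands round-trip agreement to a relative `1e-10` on a
24-point grid. Degenerate observed cells are handled explicitly rather
than silently:

- `Pc` of exactly 0, 1/2 or 1 leaves the inverse undefined.
  `edge_correct()` nudges such cells by the minimal perturbation
  `1/(2n)` (a 32-trial perfect cell becomes 63/64) and flags them.
- Cells with fewer than two correct trials or zero RT variance are
  flagged `degenerate` and carried through with `NA` parameters —
  `estimate_all()` never drops rows, so downstream balance checks can
  name the offending cells.
- Negative `Ter` estimates (possible in small noisy cells) are retained
  and visible, never clamped; clamping would bias cell means fed to the
  ANOVAs.

The estimation cell is the full 3-factor cell (expression × response ×
face gender, 32 trials), the granularity at which the parameter ANOVAs
operate.

## Bayes factors

Two computational routes, chosen for self-containedness and testability:

- **Model terms** (`run_bayes_anova()`): every main effect and
  interaction of the mixed 2×2×2×2 design is compared, one term at a
  time, against a null model containing only a participant random
  intercept. Both models are fitted by maximum likelihood (`lme4`) and
  the Bayes factor is the BIC approximation
  `BF10 = exp((BIC_null − BIC_term)/2)`, which corresponds to a unit
  information prior. Because all factors are two-level and sum-coded
  (+1/−1), each term is a single column and "null plus term" is
  well defined without marginality constraints. The approximation is
  invariant to affine changes of the dependent variable and is
  seed-free.
- **Paired contrasts** (`jzs_ttest_bf()`): the exact
  Jeffreys-Zellner-Siow Bayes factor — Cauchy prior with scale
  `sqrt(2)/2` on the standardised effect, Jeffreys prior on the variance
  — computed by adaptive quadrature (relative tolerance `1e-8`) of the
  inverse-gamma mixture representation. The tests check it against an
  independent quadrature route (noncentral-t sampling density integrated
  against the Cauchy prior) to four significant digits.

Mixed-model Bayes factors computed with full g-priors over all effects
(as dedicated Bayes-factor packages do) will differ numerically from the
BIC route; the package's inferential claims are therefore about
direction and evidence category, not about matching any particular
package's numbers.

Evidence labels follow the Jeffreys bands: BF in (1, 3.2] anecdotal,
(3.2, 10] moderate, (10, 100] strong, above 100 decisive, with boundary
points assigned to the lower band ("between x and y" read as half-open
above); Bayes factors below 1 are labelled by banding the reciprocal
with a `null-` prefix.

Effect sizes for paired contrasts are `dz = mean/SD` of the differences.
The 95% HDI comes from the analytic posterior under a normal likelihood
with the Jeffreys reference prior: `sigma^2 | data` is scaled
inverse-chi-squared and `mu | sigma^2, data` normal, so `mu/sigma` draws
are exact; the HDI is the narrowest interval containing 95% of 100,000
seed-fixed draws (sorted-window scan). Follow-up 2×2 interaction tests
within a gender group (`simple_interaction_followup()`) use the JZS test
on the per-participant double-difference contrast, which is the exact
within-subject analogue of the interaction term.

`compare_group_means()` is a classical one-way ANOVA with partial eta
squared, used for the BIS/BAS gender comparisons.

## Accuracy: binomial GEE

Accuracy is modelled at trial level (Bernoulli) with a marginal logistic
regression fitted by generalised estimating equations, exchangeable
working correlation, and sandwich (robust) standard errors; predictors
are sum-coded so coefficients align with ANOVA effects. No GEE solver is
imported: the estimating equations, the moment estimator of the working
correlation and the sandwich covariance are implemented directly, with
the exchangeable inverse computed analytically via Sherman-Morrison.
Convergence is declared when the maximum relative coefficient change
drops below `1e-8` (at most 100 iterations); the singleton-cluster case
reduces exactly to ordinary logistic maximum likelihood, which the tests
verify against `glm()` to `1e-6`. Aggregating trials to binomial counts
per cell would give the same likelihood; the trial-level form keeps the
clustering bookkeeping simple.

## Response times: ex-Gaussian regression

For the BIS/BAS moderation analysis, correct-response RTs (seconds) are
modelled as ex-Gaussian — Normal(`mu`, `sigma`) plus
Exponential(`tau`) — with `mu` a linear function of treatment-coded
expression × response × participant-gender × covariate terms (reference
levels angry, push, male) and the questionnaire covariate centred and
scaled to 2 SD so its slope is comparable to the factor contrasts.

A full random-slopes mixed ex-Gaussian model is deliberately out of
scope. Instead, participant heterogeneity is absorbed by fixed
per-participant intercept offsets with shared `sigma` and `tau`. One
identifiability consequence follows: columns constant within a
participant (participant gender, the covariate, and their product) lie
in the span of the participant dummies and are dropped from the
coefficient table. The scientifically interesting 4-way slope
(e.g. happy × pull × female × BIS) varies within participants and
remains identified; the simulation tests recover its sign reliably and
cover a zero slope at the nominal rate.

Fitting is by BFGS on `(beta, log sigma, log tau)` with the analytic
gradient; standard errors come from the observed information
(`optimHess`). Two numerical guards matter: the likelihood returns a
large penalty outside `sigma, tau` in `[1e-4, 10]` seconds (degenerate
scales for RT data, and the region where the exact exponent suffers
catastrophic cancellation), and the density switches to its Gaussian
limit `N(mu + tau, sqrt(sigma^2 + tau^2))` when `tau < 0.05 sigma`,
where the exact expression is numerically unusable. Moment-based
starting values (skewness for `tau`) initialise both `fit_exgauss_ml()`
and the regression.

## Posterior-predictive fit assessment

`posterior_predict()` simulates (by default) 10,000 Wiener trials from
each participant-by-cell parameter estimate; `fit_summary()` compares
observed and predicted medians and 5th/95th percentiles per cell,
separately for correct and error responses, and reports the proportion
of cells whose observed median falls inside the predicted 5-95% band.
Percentiles use linear interpolation between order statistics (R type
7). Cells with no observed errors are flagged not-assessable for the
error stream rather than dropped — with accuracies above 90% such cells
are common, and error-stream fit summaries rest on few trials. Because
the symmetric-start model implies identical correct and error RT
distributions, the error stream is predicted from the same fitted
parameters; a worse error-stream fit is an expected, visible model
limitation, not an implementation artefact. `autoplot()` draws the
observed-circles / predicted-crosses figure with observed 5-95% bars.

## The synthetic-data generator

`default_scenario()` defines the ground truth the generator emulates;
its values were chosen once, from the study design the package targets,
and are not tuned:

- **Design**: 16 practice + 2 × 128 main trials per participant; 8
  identities × 2 expressions; mapping alternating between main blocks
  with per-participant randomised block order; 32 trials per 3-factor
  cell.
- **Female drift rates** are the four printed condition means of the
  target study (angry/push 2.16, angry/pull 1.85, happy/pull 2.31,
  happy/push 2.12), constant across face gender; **male drift rates**
  show only a happy (2.10) > angry (1.90) difference, so the
  expression × response interaction is a female-only effect.
- **Non-decision times** start at 0.35 s, reduced by 30 ms for female
  angry/push (the avoidance-compatible response) and by 30 ms for
  gender-congruent faces (angry-male, happy-female) in female
  participants. **Boundary separation** is 1.2, raised by 0.15 for
  female participants viewing angry male faces. These magnitudes
  reproduce the qualitative pattern (direction and rough effect size of
  the group differences), which is all the downstream tests assert.
- **Heterogeneity**: participant-level additive offsets on `v`
  (SD 0.40), `a` (SD 0.12) and `Ter` (SD 0.04), shared across that
  participant's cells — typical between-participant spreads for this
  kind of task; floors at `a = 0.3`, `Ter = 0.05` keep rare extreme
  draws inside the parameter space.
- **Contaminants**: 3% of trials get response times replaced uniformly
  on [50, 199] ms (half) or [2501, 4000] ms (half), exercising both
  trimming tails at roughly the removal rate reported for real data.
- **BIS/BAS**: integer questionnaire totals from gender-specific
  truncated normals (BIS on [7, 28], female mean 23.32 / SD 3.09, male
  19.29 / 4.21). The underlying normal mean is calibrated by
  root-finding so that the *truncated* mean equals the target — naive
  truncation would undershoot by ~0.4 points near the upper bound. BAS
  totals are split into Drive/Fun/Reward subtotals that sum exactly.

What the generator does **not** emulate — and hence what passing tests
cannot certify about real data: response errors arise only from the
diffusion hitting the wrong boundary (no lapses or fast guesses beyond
the injected contaminants), there is no practice or fatigue drift across
blocks, no trial-to-trial parameter variability (`sv`, `sz`, `st0`), no
item effects of the eight face identities, and BIS/BAS scores are
independent of the response-time parameters under the default scenario.

## Pipeline and reproducibility

`run_pipeline()` executes acquire → exclude → trim → summarise →
estimate → infer → fit-assess, writing tidy CSVs, a markdown report and
a JSON manifest (package version, seed, configuration, exclusion and
trimming tallies). Every stochastic stage consumes a sub-seed derived
deterministically from the master seed and the stage name (a small
polynomial string hash mod 2^31 − 1), so adding a stage never perturbs
earlier stages' random streams and identical configurations reproduce
outputs byte for byte — the test suite diffs two complete runs.

Problem sizes used in the validation suite were chosen to make each
check sharp at desk scale: 50,000 trials for simulator calibration and
drift-rate recovery (Monte-Carlo SE on recovered drift well below the
0.05 recovery tolerance), 32 + 32 participants for the end-to-end
qualitative reproduction (the target study's scale), 20 seeds for its
replication rate, and 10,000 draws for distribution-recovery checks.

## Known limitations

- The EZ estimator ignores starting-point bias and parameter
  variability; data generated by a fuller process would bias its
  estimates. That is a property of the method being replicated, not a
  bug, and the posterior-predictive check is the designed diagnostic.
- The BIC Bayes factor uses a unit-information prior; its numerical
  values are systematically more conservative than full JZS mixed-model
  Bayes factors for small effects.
- The ex-Gaussian regression's fixed-intercept simplification cannot
  estimate purely participant-level effects (they are absorbed), and
  shared `sigma`/`tau` understates participant differences in RT shape.
- The GEE implementation supports the exchangeable structure only —
  adequate for participant-clustered accuracy data, not a general GEE
  replacement.
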