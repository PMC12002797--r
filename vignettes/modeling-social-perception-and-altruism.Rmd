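---
title: "Modeling social perception and altruistic choice with multi-attribute diffusion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling social perception and altruistic choice with multi-attribute diffusion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialddm)
```

# The scientific problem

People help those they perceive as deserving (merit) or in need — but people
differ enormously in those perceptions, and in how the perceptions translate
into costly action. `socialddm` implements a computational account of this
pipeline in three layers:

1. **A social-perception model.** Speeded yes/no judgments ("does this person
   deserve help?" / "need help?" / a factual control, "use both hands?") are
   modelled as drift-diffusion decisions whose drift combines a
   person-specific *evidence bias* with *sensitivity-weighted normative
   evidence*.
2. **An altruistic-choice model.** Accept/reject decisions over monetary
   proposals are modelled as diffusion decisions whose drift weights the
   proposal's attributes — payoff for self, payoff for the partner, and
   fairness — with weights that shift with the partner's merit and need.
3. **A linking layer.** Subject-level summaries from both tasks (sensitivities,
   biases, attribute-weight change scores, generosity fractions, a neural
   covariate) are related through non-parametric correlations with FDR
   control, condition contrasts, a mixed-effects logistic regression of
   generous choice, and a perception-to-action linking regression.

All three layers run on synthetic cohorts produced by seeded generators that
reproduce both tasks' designs, so the full analysis is testable without any
external data.

# The diffusion engine

Both models share a two-boundary Wiener process: momentary evidence
accumulates with constant drift $v$ and unit-variance Gaussian noise between
absorbing boundaries at $0$ and $a$, starting at $w \cdot a$; the observed
response time adds a non-decision time `ndt`. The engine provides

- the closed-form probability of absorbing at the upper boundary,
  $P = \dfrac{1 - e^{-2 v w a / \sigma^2}}{1 - e^{-2 v a / \sigma^2}}$
  (continuous limit $w$ at $v = 0$);
- the first-passage-time density via the classical small-time/large-time
  series for the lower boundary, switching to whichever expansion needs fewer
  terms for a truncation error below $10^{-7}$; the upper boundary follows by
  the reflection $f_\text{upper}(t \mid v, a, w) = f_\text{lower}(t \mid -v, a, 1-w)$;
- an Euler–Maruyama simulator (step `dt`, default $10^{-3}$ s for data
  generation, $10^{-4}$ s in oracle tests).

**Noise-scale convention.** The noise SD is fixed at $\sigma = 1$; drifts,
biases, sensitivities, attribute weights and thresholds are all identified
relative to this scale. This resolves the standard scaling degeneracy of the
model.

**Simulator continuity correction.** Discrete crossing detection misses
excursions between steps, biasing first-passage times upward by
$O(\sqrt{dt})$. The simulator therefore tests the path against thresholds
shifted inward by $0.5826\,\sigma\sqrt{dt}$ (the Broadie–Glasserman–Kou
correction). With the correction the simulator agrees with the closed forms
to $|\Delta p| \lesssim 0.003$ and KS distance $\lesssim 0.008$ at
$dt = 10^{-4}$ with $10^5$ paths; without it the discretization bias alone
exceeds a KS distance of 0.01 at small boundary separations. The correction
can be disabled (`correct_boundary = FALSE`).

**Numerical floors.** A trial whose observed RT is at or below `ndt` has zero
density; its log-likelihood contribution is floored at $-10^{10}$ (not
$-\infty$) so bounded optimizers can reject the region gracefully. Inside the
optimizer bounds (`ndt` $\le$ min RT $- 0.01$ s) the floor is never active.
Paths that fail to cross either boundary before `max_time` (20 s) are
returned flagged, never dropped.

# The social-perception model

For a judged condition $c$ (merit, need, control) and a stimulus with
mean-centered normative evidence $(M, N, C)$, the drift is

$$v = \mathrm{Bias}_c + S_{c,\mathrm{merit}} M + S_{c,\mathrm{need}} N + S_{c,\mathrm{control}} C.$$

"Yes" maps to the upper boundary in every condition. Each condition carries
its own boundary separation, non-decision time and start fraction, giving 21
free parameters per subject (3 biases, the 3×3 sensitivity matrix, 3×
`a`/`ndt`/`z`). The *task-relevant* sensitivities are the diagonal entries
$S_{c,c}$; the off-diagonal entries capture inadvertent use of task-irrelevant
evidence.

Normative evidence is the per-image proportion of "yes" responses from an
independent rater sample, mean-centered over the full 64-image set; the
centering means are stored with the table so fits are reproducible.
Responses missing or beyond the 2.0 s display window are excluded from the
likelihood (the response window is a config value).

**Estimation.** The likelihood factorises over conditions, so each
condition's seven parameters are estimated by bounded L-BFGS-B
(`S ∈ [−10, 10]`, `Bias ∈ [−5, 5]`, `a ∈ [0.3, 5]`, `z ∈ [0.05, 0.95]`,
`ndt ∈ [0.05, min RT − 0.01]`) with multi-start (default 8 starts). The first
start is data-driven: with $w = 0.5$ the asymptotic yes-rate is
$\mathrm{logistic}(v a / \sigma^2)$, so logistic-regression coefficients of
choices on the centered evidence, divided by a nominal threshold, initialise
$(\mathrm{Bias}, S)$; the remaining starts are jittered. An optional
*shrinkage* mode implements a two-stage empirical-Bayes MAP: first-stage MLEs
supply Normal hyper-means and hyper-SDs (floored at 0.1) for every parameter
and each subject is refitted under those priors. This approximates
hierarchical pooling without a hierarchical sampler; it is an approximation,
not a replication, of a fully Bayesian fit.

# The altruistic-choice model

A proposal offering `offer_self` / `offer_other` dollars against a constant
default of \$20 for both players is encoded as
`Self = (offer_self − 20)/10`, `Other = (offer_other − 20)/10`,
`Fairness = −|Other − Self|` (computed on the rescaled differences; a
raw-dollar convention would simply rescale the fairness weight by 10). The
drift is

$$V = w_0 + w_\text{self}\,\mathrm{Self} + w_\text{other}\,\mathrm{Other} + w_\text{fairness}\,\mathrm{Fairness},$$

with accept on the upper boundary. Each of the four weights (including the
value constant $w_0$) has a baseline at the reference condition — **unknown
merit, low need**, the natural midpoint given that the merit manipulation
raises or lowers merit relative to an uninformative partner — plus three
additive change parameters: merit→high, merit→low, need→high. Deltas are
weight-specific (12 in total) and compose linearly with no merit×need
interaction; `a`, `ndt`, `z` are shared across the six cells, giving 19
parameters. The observed four-point response scale (strong no … strong yes)
is collapsed to binary accept/reject for modelling; confidence is retained in
the data model but unused.

Change scores are `Δw(merit) = δ_merit_high − δ_merit_low` and
`Δw(need) = δ_need_high` per attribute; the *overall* weight is the
unweighted mean of the six condition-resolved weights (the averaging scheme
is a documented choice; the six cells are balanced by design, so weighting
makes no difference on complete designs).

Estimation mirrors the perception model (19-dimensional bounded L-BFGS-B,
multi-start with a logistic-regression start, optional shrinkage). An empty
merit×need cell is an error naming the cell; cells below 25 usable trials
warn.

# Behavioural metrics

A choice is *generous* if it accepts a proposal favouring the partner
(`Self < Other`) or rejects one favouring oneself (`Self > Other`).
Equal-payoff proposals involve no trade-off: they are unclassifiable,
excluded from fractions, and counted. The cold-pressor buy-out rule removes
10 percentage points of CPT probability per dollar spent, floored at 0%.
Data-quality screening drops subjects whose identical response exceeds 90% of
trials (strictly greater, as the rule is stated) and, optionally, subjects
with too few trials.

# The statistics layer

- **Generous-choice GLMM**: `generous ~ need * merit + (1 | subject)`,
  logistic link, Laplace approximation (`lme4::glmer`), reference levels low
  need / low merit; LRTs against the random-intercept-only null and the
  main-effects model; Wald 95% CIs. The reported pseudo-$R^2$ is the
  Nakagawa marginal/conditional variant with the logistic
  distribution-specific variance $\pi^2/3$. Suspected complete separation
  (|coefficient| or SE > 10) triggers a flagged refit with light cell-mean
  data augmentation (half a success and half a failure per design cell).
- **Condition contrasts**: paired Wilcoxon signed-rank tests of each
  attribute weight, high vs low merit and high vs low need, BH-adjusted over
  the six contrasts; exact distribution for n ≤ 25 without ties, Normal
  approximation otherwise; all-zero differences are undefined and reported
  with p = 1 and a flag.
- **Correlations**: Spearman with midrank ties; exact p for n ≤ 10 (no
  ties), t-approximation otherwise; BH within the declared family. Families
  mirror the analysis batteries (sanity checks of change scores, sensitivity
  battery, bias battery) and are explicit in `cross_task_correlations()`.
- **Outlier rule**: single-pass removal of values beyond 3 SDs of the
  full-vector mean, applied per variable before each correlation; zero
  variance removes nothing.
- **Linking regression**: OLS `Δw ~ 1 + S_merit + rTPJ` with 95% CIs and an
  LRT against the intercept-only model; predictor correlation above |0.99|
  is flagged as collinear.
- **Partial correlations**: Spearman correlation of the OLS residuals of the
  two variables' midranks on the control's midranks; a constant control
  reduces to the plain Spearman, flagged.

# The synthetic cohort generators

The generators define the conditions under which the package is exercised:

- **Task designs.** The perception task presents 64 images once per
  condition (192 trials); the altruism task has 300 trials in 5 runs of
  three 20-trial partner blocks (100 trials per partner, partner order
  rotated across runs and subjects), need high on half the trials per
  partner, cues of 80% or 20% plus symmetric uniform jitter on ±4 points
  (the symmetric reading of the "±4" band), and proposals drawn from a
  \$5–\$31 base grid concentrated (80%) in the two trade-off quadrants then
  jittered by \$0–\$4, spanning \$5–\$35.
- **Parameter distributions** default to the reported group statistics of
  the study the package models: task-relevant sensitivities
  2.84 ± 1.02 (merit), 3.28 ± 0.75 (need), 4.40 ± 0.69 (control); biases
  0.33 ± 0.47, −0.17 ± 0.39, 0.09 ± 0.36 with merit–need bias correlation
  0.73; overall attribute weights near 0.97 (self), 0.22 (other),
  0.35 (fairness). Unreported quantities are package defaults: off-diagonal
  sensitivities 0.5 ± 0.3 (task-irrelevant evidence intrudes weakly),
  thresholds/timing (`a` 1.5 ± 0.25 and 1.8 ± 0.3, `ndt` 0.35/0.5,
  `z` 0.5 ± 0.05) typical of speeded binary and value-based tasks.
- **Normative evidence** uses Beta marginals with a Gaussian copula for the
  merit–need correlation (0.3). Concentrations are dimension-specific:
  merit κ = 2 (deservingness must be inferred indirectly, so raters
  disagree moderately), need κ = 0.8 and control κ = 0.5 (need is signalled
  directly and concretely per image and the control judgment is factual, so
  per-image rater proportions are strongly bimodal). These choices matter:
  the dispersion of the normative evidence sets the Fisher information for
  the sensitivities at the fixed 64-trials-per-condition design.
- **Change-parameter heterogeneity** is 0.30 SD per delta. This is
  deliberately larger than single-subject estimation noise (~0.2 at 300
  trials): observed correlations near 0.9 between model change scores and
  behavioural generosity changes in cohorts of ~28 are only possible when
  true between-subject variance dominates estimation noise, so a smaller
  heterogeneity would contradict the analyses the generator exists to
  exercise.
- **Cross-task couplings** for linked cohorts: merit sensitivity drives the
  merit change parameters of other-regard (positively) and self-regard
  (negatively) at 0.6 of each delta's SD; merit bias drives baseline
  other-regard at 0.6 SD; the synthetic rTPJ covariate is
  `1.0 × standardize(S_merit) + N(0, 1)`; the inter-task delay is uniform on
  27–663 days.

**What the generators do not emulate**: real images and their rater sample
(only aggregate proportions), sequential/learning effects across trials,
response-scale usage (confidence), RT contaminants (fast guesses, lapses),
and any true neural measurement process. Passing recovery and sign tests on
these cohorts therefore demonstrates the estimators and statistics are
correct and calibrated under the model's own assumptions — not that the model
is true of real data.

# Verification strategy and problem sizes

The test suite checks, among others: conservation and reflection identities
of the density; agreement of closed form, series density, and brute-force
Euler–Maruyama simulation on a 12-spec grid ($10^5$ paths, $dt = 10^{-4}$);
parameter recovery on 30 synthetic perception subjects (192 trials each) and
20 altruism subjects (300 trials each); calibration of the GLMM likelihood-
ratio test under a null generator (50 replicates) and of the linking
regression's CIs (100 replicates at n = 25); brute-force cross-checks of BH,
Spearman and the signed-rank test on small instances; and sign reproduction
of the cross-task pattern on a 40-subject linked cohort (sized so that a
sign check on a doubly-attenuated correlation of moderate size is reliable). Recovery quality is
summarised as the correlation between generating and recovered values pooled
within a parameter class (the three task-relevant sensitivities, the three
biases, the four baseline weights, the twelve change parameters), the way
recovery scatters are usually read; per-parameter correlations are computed
alongside. The heavy harnesses use 3–4 optimizer starts after verifying on
pilot subjects that additional starts reach the same optima; the exported
default remains 8.

# Known limitations

- Per-parameter recovery of the need sensitivity is information-limited at
  the fixed design (64 trials per condition): the MLE's replicate-dataset SD
  is comparable to the population SD, capping its individual true-vs-fitted
  correlation near 0.7 regardless of estimator. Pooled class correlations
  clear 0.8.
- The shrinkage mode is a two-stage approximation; it does not propagate
  hyper-parameter uncertainty.
- The GLMM's Laplace approximation can be slightly anticonservative for
  small cohorts; the calibration test bounds the realised false-positive
  rate at the sizes used.
- Across-trial parameter variability (sv, st, sz), collapsing bounds and
  attention-weighted variants are out of scope by design.
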