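---
title: "Hybrid text + structured multitask modelling of 10-year cardiovascular risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid text + structured multitask modelling of 10-year cardiovascular risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskfusion)
```

## The modelling problem

`riskfusion` develops and audits 10-year cardiovascular-disease (CVD) risk
models over fixed-horizon prediction *episodes*: a patient who is CVD-free
at an entry age contributes one record per 5-year entry age between 40 and
75, with predictors resolved at entry and a binary outcome plus a
time-to-event (TTE) in days, administratively censored at 3650 days.
Two objectives are optimized jointly:

* **event classification** — will a CVD event occur within the horizon?
  (thresholded clinical decisions, AUROC), and
* **risk ranking** — who fails earlier? (Cox-style partial likelihood,
  concordance).

The model is a dual-branch hybrid. Categorical and ordinal predictors are
rendered into a short clinical narrative by deterministic templates (age
class, BMI class, ethnicity, smoking status, prestratified risk group, and
a comma-separated comorbidity history). A compact bidirectional
transformer encodes the narrative; a ReLU MLP with dropout encodes the
min-max-scaled structured features. A linear *alignment* projection maps
each branch to a shared fusion width; the two projected tokens pass
through a stack of multi-head self-attention layers with residual
connections and layer normalization, the two positions are mean-pooled,
and two independent linear heads emit a classification logit (with
temperature scaling) and a scalar log hazard.

## The multitask loss

The classification head is trained with the focal loss
$\ell_f = -w\,\alpha\,(1-p_t)^\gamma \log p_t$ (with $p_t = p$ for events
and $1-p$ otherwise, and per-class weights $w$ from the balanced scheme),
and the hazard head with the negative log Cox partial likelihood over the
mini-batch (Breslow ties, normalized by the number of events so its scale
does not depend on batch size; an Efron option exists). The two are
combined with learnable homoscedastic task uncertainties:

$$
L \;=\; \frac{L_{\text{focal}}}{2\sigma_f^2}
      + \frac{L_{\text{cox}}}{2\sigma_c^2}
      + \log \sigma_f + \log \sigma_c .
$$

At fixed component losses the minimizer satisfies $\sigma^2 = L$, which
the test suite verifies against numeric minimization. The $\sigma$
parameters are stored on the log scale (positivity by construction),
initialized at $\sigma = 1$, and *frozen for the first 10 epochs* so that
the early loss ratio is fixed at $1/2 : 1/2$; they become learnable
afterwards. Focal defaults are $\gamma = 2$, $\alpha = 0.25$ (exposed in
the configuration; the balanced class-weight scheme is the
$\beta$-exponent family with $\beta = 0$ as default, so the
reference-rate scaling is off unless requested).

Training uses AdamW (decoupled weight decay $10^{-4}$, initial learning
rate $3 \times 10^{-4}$), global gradient-norm clipping at 1.0, a cosine
annealing schedule with warm restarts (first cycle 10 epochs, doubling),
early stopping on the validation composite (AUROC + C-index)/2 with
patience 5 and a 12-epoch floor before stopping may trigger (warm
restarts make the validation trajectory non-monotone within a cycle, and
the first cycle ends exactly where the uncertainty parameters unfreeze,
so stopping inside the first annealing trough would discard the restart
the schedule is built around), and model selection by the same composite
with ties resolved to the earliest epoch. The batch size defaults to 64, which respects the
Cox risk-set floor (risk sets below 64 would make the partial-likelihood
batches uninformative) while giving desk-scale cohorts enough optimizer
steps per epoch. All of these are package choices where the training
contract leaves room; learning rate and weight decay follow the stated
contract.

Because no automatic differentiation stack exists for R in this
environment, the forward and backward passes of every layer (embeddings,
pre-norm transformer blocks with padding-masked attention, MLP, fusion
attention, heads, temperature, and both loss terms) are written
explicitly; all analytic gradients are finite-difference-checked in the
test suite at $10^{-4}$ relative tolerance or better.

## The synthetic cohort generator

No real primary-care extract can ship with the package, so all studies
run on a simulator whose defaults emulate the population the method
targets:

* **marginals** — sex ratio, 9-category ethnicity mixtures (a
  predominantly White `development` preset and a minority-enriched
  `spatial` preset with ~65% White), smoking, prestratified risk group,
  13 comorbidity prevalences, and means/SDs of BMI, systolic blood
  pressure and its SD, diastolic pressure, and the total/HDL cholesterol
  ratio, all sex-specific;
* **event process** — one latent event age per patient, drawn from a
  Weibull proportional-hazards model anchored at age 40 with shape 1.2
  (hazard rising with age) and sex-specific scales calibrated so the
  10-year event probability at the covariate reference is 8.19% in men
  and 4.91% in women; the log hazard is $x \cdot \beta$ over z-scored
  latent traits (systolic pressure, lipid ratio, BMI, Townsend
  deprivation) plus ever-smoker and treated-hypertension indicators;
* **episodes** — entries at ages 40–75 in 5-year steps for patients
  registered and event-free at entry (years are 365 days, integer entry
  ages); events within a 183-day grace window after the horizon keep a
  positive label with the TTE clipped to 3650; a patient's episodes are
  mutually consistent because they all derive from the same latent event
  age, and `simulate_outcomes()` draws left-truncated times from the same
  process for standalone use;
* **measurements** — each continuous predictor generates a noisy
  measurement near each eligible entry (subject to per-variable
  missingness) and, for a fraction of entries, a short prior series, so
  the windowed-resolution and linear-regression-imputation paths are
  exercised end to end.

Design notes worth making explicit:

* Nonzero true coefficients sit only on *common* covariates. A
  coefficient on a rare flag (prevalence below ~5%) cannot be estimated
  to within ±0.15 from cohorts of ~5,000 episodes (~600 events), so
  placing signal there would make parameter-recovery checks test sample
  size rather than correctness. The rare comorbidity flags instead enter
  the data (and the narratives) as realistic nuisance structure with zero
  effect.
* The treated-hypertension onset is drawn before age 40 so the at-entry
  flag always equals the covariate driving the (time-invariant) log
  hazard; other comorbidities onset between 25 and 65 and accumulate
  with entry age.
* Coefficient recovery is evaluated with a **sex-stratified** linear Cox
  fit on the generator's own standardized covariates
  (`true_covariate_matrix()`): the generator has sex-specific baseline
  hazards, so an unstratified fit exhibits classical omitted-stratum
  confounding (smoking prevalence differs by sex), and the resolved
  episode values add errors-in-variables attenuation that is a property
  of the measurement model, not of the estimator under test. The
  noisy "modeller view" remains what the neural model consumes.
* The `signal` multiplier scales $\beta$. The default 1 produces
  realistic moderate discrimination (oracle AUROC around 0.75-0.80 on
  held-out episodes). The strong-signal setting used by the end-to-end
  learnability checks is 3, chosen so that the *oracle* (true linear
  predictor) discrimination on a held-out partition is ≈0.86: the
  learnability bar (validation AUROC 0.70, C-index 0.65) then sits far
  below what a correct learner can reach, and the check measures
  learning, not sampling luck on a ~250-episode validation set.
* Multi-episode patients induce within-patient clustering; splits
  therefore keep all of a patient's episodes in one partition by default
  (`group_split_by_patient`), a leakage guard the episode design would
  otherwise violate silently.

What the simulator does *not* emulate: real measurement panels and visit
processes (measurements cluster around entries by construction),
informative censoring (censoring is purely administrative), competing
risks, temporal drift of clinical practice, correlation between
comorbidities, or free-text notes beyond the closed template vocabulary.
Passing tests on this cohort demonstrate that the machinery is correct
and that the estimators recover known structure — not that the model's
clinical performance on real data would match.

## Preprocessing choices

Continuous predictors resolve to the nearest measurement within ±183
days of entry; failing that, an ordinary-least-squares line through at
least 3 prior measurements within a 730-day look-back is evaluated at the
entry day ("2-year span" is read as this look-back; duplicate days are
averaged first). Smoking falls back to the most recent prior record and
medication flags to any prior prescription; absence is information (flag
0), not missingness. Quality control removes episodes with implausible
continuous values (defaults: SBP 60–250 mmHg, DBP 30–150, BMI 15–70,
TC/HDL 1–12; configurable — no thresholds are inherited from elsewhere).
Remaining unresolved continuous values take the training-partition
median. Min-max scaling is fitted on the training partition only;
non-training values clip to [0, 1] and constant features map to 0.
Splits are stratified by event × sex at a 70:15:15 ratio (the ratio is
configurable; where two conventions conflict, the one governing the
reported experiments wins and is the default).

## Evaluation and fairness audit

Discrimination: rank-based AUROC (half-credit ties) with percentile
bootstrap CIs (B = 1000), and Harrell's concordance on the log-hazard
head (computed via `survival::concordance`, oracle-checked against
exhaustive pair enumeration). Calibration: isotonic
(pool-adjacent-violators via `stats::isoreg`) fitted on validation and
applied to test, decile tables, and the plain binary Brier score at the
horizon — censoring here is administrative at exactly 3650 days, so
inverse-probability-of-censoring weighting is unnecessary by design
(available behind a flag for general censoring). Classification metrics
are reported at a threshold chosen by Youden's J on validation unless a
fixed threshold is supplied. Risk stratification uses sex-specific
calibrated-probability thresholds (men ≥ 40%, women ≥ 34%, both
inclusive); Kaplan-Meier curves carry Greenwood bands with segments
suppressed after the at-risk count drops below 10, and separation is
tested by the log-rank statistic.

The fairness audit computes per-subgroup AUROC (bootstrap variance by
default; Hanley-McNeil closed form behind a flag) across the 9 ethnicity
categories, two broad rollups (White / South Asian = Indian + Pakistani +
Bangladeshi / Black = Caribbean + African, with Chinese, Other Asian and
Other unmapped; and an alternative folding all Asian groups together —
both conventions are provided because the source conventions differ),
and Townsend quintiles/deciles computed from the cohort's own empirical
distribution. Heterogeneity is quantified by Cochran's
$Q = \sum w_i (\theta_i - \bar\theta_w)^2$, $w_i = 1/v_i$, and Higgins'
$I^2 = 100 \cdot \max(0, (Q - (k-1))/Q)$, cross-checked against a
fixed-effect meta-analysis.

## Problem sizes used by the shipped studies

The packaged checks and the acceptance script run at desk scale, chosen
so a complete run fits comfortably on one CPU: the end-to-end
learnability study trains the tiny encoder (2 layers, 4 heads, width 64,
token budget 64) on a strong-signal cohort of 430 patients (≈2,000
episodes) for up to 30 epochs with patience 8 (two extra beyond the
default so the uncertainty-unfreezing stage after epoch 10 is always
observed); coefficient recovery uses five cohorts of ≈5,000 episodes
each. Bootstrap CIs use B = 1000 in the acceptance script and smaller B
in unit tests.

## Known limitations

* The text encoder is randomly initialized by default ("tiny" mode);
  pretrained weights can be loaded from a local checkpoint, but no
  pretraining corpus or downloads are part of the package, so the
  semantic-transfer benefits a pretrained language model would bring are
  out of scope.
* The narrative vocabulary is closed (template-generated); the
  WordPiece-style tokenizer falls back to character continuations for
  out-of-vocabulary words but has no learned merges.
* Temperature is trained jointly rather than post hoc; the two
  conventions differ and the package picks joint training for
  simplicity, with the fixed option available.
* The Cox branch assumes proportional hazards within sex strata and
  handles ties by Breslow's approximation by default.
* `select_model` and early stopping share the composite criterion; with
  very small validation partitions both are noisy, which is why the
  shipped studies use strong signal and report the stochastic checks as
  such.
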