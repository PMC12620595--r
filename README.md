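# riskfusion

Hybrid text + structured multitask modelling of 10-year cardiovascular
risk, with a synthetic EHR cohort simulator, a full preprocessing and
training pipeline, survival-aware evaluation, and a subgroup fairness
audit.

## Who this is for

Methodologists and clinical-ML engineers who want a fully inspectable,
dependency-light implementation of the "dual-branch" recipe for long-term
risk prediction from primary-care records: render the categorical slice of
an electronic health record into a short clinical narrative, encode it with
a compact bidirectional transformer, encode the scaled continuous/binary
features with an MLP, fuse the two representations through stacked
multi-head self-attention, and train the fused model *jointly* for
10-year event classification and time-to-event ranking. Real primary-care
extracts are access-restricted, so the package ships a cohort simulator
with known ground truth instead: every component can be exercised,
stress-tested and audited end to end on one CPU.

## The model and loss

For episode $i$ with narrative $x^{(t)}_i$ and structured features
$x^{(s)}_i$, the network produces a classification logit $z_i$
(temperature-scaled, $p_i = \sigma(z_i/T)$) and a log hazard $h_i$. The
training objective is the uncertainty-weighted focal + Cox loss

$$
L = \frac{L_{\text{focal}}}{2\sigma_f^2} + \frac{L_{\text{cox}}}{2\sigma_c^2}
    + \log\sigma_f + \log\sigma_c,
$$

with the focal term $-w\,\alpha (1-p_t)^\gamma \log p_t$ (class-weighted,
$\gamma = 2$, $\alpha = 0.25$ by default) and the Cox term the negative
log partial likelihood over each mini-batch (Breslow ties, event-count
normalized). $\sigma_f, \sigma_c$ are learnable, stored on the log scale,
frozen at 1 for the first 10 epochs and adaptive afterwards. Optimization
is AdamW (lr $3\times10^{-4}$, weight decay $10^{-4}$) with cosine
annealing and warm restarts, gradient clipping, early stopping, and model
selection by the mean of validation AUROC and C-index. All forward and
backward passes are hand-written R matrix code, finite-difference-checked
in the test suite.

## Worked example

```r
library(riskfusion)

co   <- generate_cohort(cohort_spec(n_patients = 400, seed = 11, signal = 3))
prep <- prepare_dataset(co, seed = 11)
prep
#> prepared_data: 1701 episodes (39 features), split 1208/250/243
#>   event rate 13.9%; class weights 0.58 / 3.64

fit <- train_model(prep, model_config(max_tokens = 64, seed = 11),
                   train_config(epochs = 30, seed = 11, batch_size = 64))
ev  <- evaluate_model(fit, prep, B = 200, seed = 1)
ev$report
#> Metric report
#>   AUROC: 0.871 (95% CI 0.808-0.920)
#>   C-index: 0.819
#>   Brier: 0.162 (calibrated 0.090)
#>   At threshold 0.489: accuracy 0.844, recall 0.647, specificity 0.876
#>   Log-rank (high vs low risk): chisq 53.00, p 3.3e-13
```

Reading the output: the cohort of 400 synthetic patients yields 1,701
10-year episodes (one per CVD-free 5-year entry age). After training, the
selected checkpoint discriminates events on the held-out test partition
with AUROC 0.871 and ranks times to event with concordance 0.819; isotonic
recalibration (fitted on validation) brings the Brier score from 0.162 to
0.090; and splitting patients into high/low predicted-risk groups at the
sex-specific thresholds (men ≥ 40%, women ≥ 34%) separates the
Kaplan-Meier curves decisively (log-rank p < 0.001). Because the simulator
is a strong-signal preset (`signal = 3`), these numbers reflect machinery
working correctly on favourable data, not expected real-data performance.

The generator's coefficients can be recovered from the episodes with the
package's own Cox ranking loss:

```r
eps <- build_episode_table(co)
X   <- true_covariate_matrix(eps, co)
fit_cox_linear(X, eps$tte_days, eps$event, strata = eps$sex)$beta
```

A fairness audit over any subgrouping returns per-subgroup AUROCs with
Cochran's Q and Higgins' I²:

```r
audit_subgroups(ev$predictions$prob, ev$predictions$event,
                deprivation_quantile(ev$predictions$townsend, 5))
```

An end-to-end experiment (simulate → prepare → train → evaluate → audit,
plus a reproducibility manifest) runs from one YAML config via
`run_experiment("run.yaml")`, or from the shell through the thin CLI in
`inst/cli/riskfusion` (subcommands `simulate`, `prepare`, `train`,
`evaluate`, `audit`, `run`, `compare`).

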