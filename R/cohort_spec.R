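# Cohort specification: population marginals, event-process parameters and
# generator settings.  Marginals mirror the development and
# minority-enriched spatial-validation populations of a UK primary-care
# cohort; values are percentages converted to probabilities and renormalized.

.ethnicity_mixture <- list(
  development = c(White = 93.68, Indian = 1.48, Pakistani = 0.965,
                  Bangladeshi = 0.24, Chinese = 0.255, `Other Asian` = 0.485,
                  `Black Caribbean` = 0.54, `Black African` = 0.325,
                  `Other ethnic group` = 2.02),
  spatial = c(White = 65.235, Indian = 8.325, Pakistani = 1.835,
              Bangladeshi = 1.265, Chinese = 1.0, `Other Asian` = 4.34,
              `Black Caribbean` = 5.945, `Black African` = 6.415,
              `Other ethnic group` = 5.64)
)

.smoking_probs <- list(
  development = list(
    male   = c(0.4573, 0.5173, 0.0061, 0.0117, 0.0076),
    female = c(0.5842, 0.3940, 0.0075, 0.0099, 0.0044)),
  spatial = list(
    male   = c(0.4710, 0.5071, 0.0047, 0.0104, 0.0067),
    female = c(0.5971, 0.3850, 0.0063, 0.0080, 0.0035))
)

.risk_group_probs <- list(
  development = list(
    male   = c(0.4197, 0.2667, 0.2163, 0.0973),
    female = c(0.5711, 0.2259, 0.1498, 0.0532)),
  spatial = list(
    male   = c(0.4454, 0.2674, 0.2053, 0.0818),
    female = c(0.6142, 0.2151, 0.1307, 0.0399))
)

# mean / sd of the continuous traits by preset and sex
.continuous_traits <- list(
  development = list(
    male   = list(bmi = c(27.45, 4.42), sbp = c(135.17, 12.30),
                  sbp_sd = c(9.05, 4.83), dbp = c(81.82, 7.42),
                  tchol_hdl_ratio = c(4.08, 0.83), townsend = c(0, 3.4)),
    female = list(bmi = c(27.18, 5.47), sbp = c(131.32, 14.83),
                  sbp_sd = c(9.87, 4.88), dbp = c(79.18, 7.93),
                  tchol_hdl_ratio = c(4.11, 0.84), townsend = c(0, 3.4))),
  spatial = list(
    male   = list(bmi = c(27.25, 4.31), sbp = c(134.79, 12.02),
                  sbp_sd = c(8.93, 4.88), dbp = c(81.75, 7.33),
                  tchol_hdl_ratio = c(4.20, 0.84), townsend = c(1.5, 3.6)),
    female = list(bmi = c(26.54, 5.30), sbp = c(129.63, 14.88),
                  sbp_sd = c(9.50, 4.79), dbp = c(78.47, 7.93),
                  tchol_hdl_ratio = c(4.19, 0.85), townsend = c(1.5, 3.6)))
)

.comorbidity_prev <- list(
  development = list(
    male = c(diabetes = 0.0475, ckd = 0.0089, fh_chd = 0.0372, af = 0.0080,
             ed = 0.0412, hiv = 0.0012, migraine = 0.0236, ra = 0.0037,
             sle = 0.0005, smi = 0.0096, antipsychotic = 0.0042,
             corticosteroid = 0.0322, treated_hypertension = 0.1383),
    female = c(diabetes = 0.0361, ckd = 0.0131, fh_chd = 0.0480, af = 0.0045,
               ed = 0, hiv = 0.0003, migraine = 0.0640, ra = 0.0089,
               sle = 0.0021, smi = 0.0096, antipsychotic = 0.0042,
               corticosteroid = 0.0468, treated_hypertension = 0.1443)),
  spatial = list(
    male = c(diabetes = 0.0382, ckd = 0.0089, fh_chd = 0.0272, af = 0.0092,
             ed = 0.0425, hiv = 0.0005, migraine = 0.0291, ra = 0.0035,
             sle = 0.0005, smi = 0.0068, antipsychotic = 0.0034,
             corticosteroid = 0.0253, treated_hypertension = 0.1272),
    female = c(diabetes = 0.0282, ckd = 0.0152, fh_chd = 0.0323, af = 0.0046,
               ed = 0, hiv = 0.0003, migraine = 0.0717, ra = 0.0079,
               sle = 0.0022, smi = 0.0084, antipsychotic = 0.0037,
               corticosteroid = 0.0387, treated_hypertension = 0.1301))
)

# Fixed reference constants used to standardize covariates inside the
# simulated log-hazard (z-scores on a stable scale, shared across presets).
.lp_reference <- list(
  bmi = c(27.3, 5.0), sbp = c(133.2, 13.7), tchol_hdl_ratio = c(4.1, 0.84),
  townsend = c(0, 3.4)
)

# Default true log-hazard coefficients on the standardized scale.  Nonzero
# effects sit on common covariates only: a coefficient on a rare (<5%
# prevalence) comorbidity flag is not estimable to useful precision from
# cohorts of the size this generator targets.
.default_beta <- c(
  sbp = 0.45, tchol_hdl_ratio = 0.35, bmi = 0.25, townsend = 0.20,
  ever_smoker = 0.25, treated_hypertension = 0.40
)

#' Specification of a synthetic cohort
#'
#' Bundles the population marginals (preset `"development"` or the
#' minority-enriched `"spatial"` validation population), the
#' proportional-hazards event-process parameters with known log-hazard
#' coefficients, censoring and grace windows, and measurement missingness
#' settings.
#'
#' @param sex_ratio_male Proportion of male patients (default 0.4717).
#' @param preset `"development"` or `"spatial"`; selects the ethnicity
#'   mixture, smoking/risk-group marginals, comorbidity prevalences and
#'   continuous trait distributions.
#' @param n_patients Number of patients to simulate.
#' @param seed Integer random seed; generation is deterministic given it.
#' @param signal Multiplier applied to the true coefficient vector; 1 gives
#'   realistic moderate discrimination, 3 the strong-signal setting used for
#'   end-to-end learnability checks (oracle discrimination well above the
#'   levels a desk-scale model must reach).
#' @param beta Named true log-hazard coefficient vector on the standardized
#'   covariate scale; defaults to the package's realistic effect set.
#' @param weibull_shape Weibull baseline shape (default 1.2, hazard rising
#'   with age).
#' @param baseline_event_rate Named vector (`male`, `female`): 10-year event
#'   probability at the covariate reference (log-hazard 0), used to
#'   calibrate the baseline scale.
#' @param horizon_days Administrative censoring horizon (default 3650).
#' @param grace_days Post-horizon grace window within which events still
#'   label the episode positive (default 183).
#' @param ethnicity_probs Optional named 9-element mixture overriding the
#'   preset; must sum to 1.
#' @param missingness Named per-variable probability that an entry window
#'   contains no measurement.
#' @param measurement_noise Named within-patient measurement noise SDs.
#' @param group_split_by_patient Keep all of a patient's episodes in one
#'   partition when splitting (default TRUE).
#' @return Object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec("development", n_patients = 100, seed = 7)
cohort_spec <- function(preset = c("development", "spatial"),
                        n_patients = 1000, seed = 1, signal = 1,
                        sex_ratio_male = 0.4717,
                        beta = NULL, weibull_shape = 1.2,
                        baseline_event_rate = c(male = 0.0819, female = 0.0491),
                        horizon_days = 3650, grace_days = 183,
                        ethnicity_probs = NULL,
                        missingness = c(bmi = 0.15, sbp = 0.08, sbp_sd = 0.20,
                                        dbp = 0.10, tchol_hdl_ratio = 0.20),
                        measurement_noise = c(bmi = 0.8, sbp = 4, sbp_sd = 1.5,
                                              dbp = 3, tchol_hdl_ratio = 0.3),
                        group_split_by_patient = TRUE) {
  preset <- match.arg(preset)
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (horizon_days <= 0) stop("configuration error: horizon must be > 0")
  if (weibull_shape <= 0) stop("configuration error: Weibull shape must be > 0")
  if (is.null(beta)) beta <- .default_beta * signal
  if (is.null(ethnicity_probs)) {
    ethnicity_probs <- .ethnicity_mixture[[preset]]
    ethnicity_probs <- ethnicity_probs / sum(ethnicity_probs)
  } else {
    if (abs(sum(ethnicity_probs) - 1) > 1e-6) {
      stop("configuration error: ethnicity mixture probabilities must sum to 1")
    }
    if (!setequal(names(ethnicity_probs), ETHNICITY_LEVELS)) {
      stop("configuration error: ethnicity mixture must name all 9 categories")
    }
    ethnicity_probs <- ethnicity_probs[ETHNICITY_LEVELS]
  }
  # Weibull scale per sex so that P(event within horizon | lp = 0) equals the
  # baseline rate: 1 - exp(-(horizon/scale)^shape) = rate.
  scale_days <- horizon_days /
    (-log(1 - baseline_event_rate))^(1 / weibull_shape)
  if (sex_ratio_male < 0 || sex_ratio_male > 1) {
    stop("configuration error: sex_ratio_male must lie in [0, 1]")
  }
  spec <- list(
    preset = preset, n_patients = as.integer(n_patients),
    sex_ratio_male = sex_ratio_male,
    seed = as.integer(seed), signal = signal, beta = beta,
    weibull_shape = weibull_shape, weibull_scale = scale_days,
    baseline_event_rate = baseline_event_rate,
    horizon_days = as.integer(horizon_days),
    grace_days = as.integer(grace_days),
    ethnicity_probs = ethnicity_probs,
    smoking_probs = .smoking_probs[[preset]],
    risk_group_probs = .risk_group_probs[[preset]],
    traits = .continuous_traits[[preset]],
    comorbidity_prev = .comorbidity_prev[[preset]],
    lp_reference = .lp_reference,
    missingness = missingness,
    measurement_noise = measurement_noise,
    entry_ages = seq(40L, 75L, by = 5L),
    group_split_by_patient = isTRUE(group_split_by_patient)
  )
  class(spec) <- "cohort_spec"
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("cohort_spec: preset '%s', %d patients, seed %d\n",
              x$preset, x$n_patients, x$seed))
  cat(sprintf("  Weibull shape %.2f, scale male %.0f / female %.0f days\n",
              x$weibull_shape, x$weibull_scale["male"],
              x$weibull_scale["female"]))
  cat("  nonzero beta:",
      paste(sprintf("%s=%.2f", names(x$beta)[x$beta != 0],
                    x$beta[x$beta != 0]), collapse = ", "), "\n")
  invisible(x)
}
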