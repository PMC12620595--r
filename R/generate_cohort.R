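# Synthetic multi-episode EHR cohort generation with known
# proportional-hazards ground truth.

#' Generate a synthetic patient cohort
#'
#' Simulates patient histories under the population marginals of the
#' specification: demographics, latent continuous traits, smoking,
#' prestratified risk group (rank-correlated with the true log hazard),
#' comorbidity onsets, a longitudinal measurement series per continuous
#' variable, and a single latent cardiovascular event age drawn from a
#' Weibull proportional-hazards process starting at age 40 with log-hazard
#' `x . beta`.  Generation is fully deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synth_cohort`: a list with `patients`
#'   (data.frame, one row per patient, including `true_lp` and
#'   `cvd_event_age`), `measurements` (data.table of
#'   `patient_id`/`variable`/`day`/`value`, days relative to the age-40
#'   anchor), and the `spec`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 50, seed = 7))
#' head(cohort$patients)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  sex <- ifelse(runif(n) < spec$sex_ratio_male, "male", "female")
  patients <- data.frame(
    patient_id = sprintf("P%07d", seq_len(n)),
    sex = sex,
    registration_age = sample(25:60, n, replace = TRUE),
    ethnicity = sample(ETHNICITY_LEVELS, n, replace = TRUE,
                       prob = spec$ethnicity_probs),
    stringsAsFactors = FALSE
  )
  # continuous latent traits by sex
  for (v in c("bmi", "sbp", "sbp_sd", "dbp", "tchol_hdl_ratio", "townsend")) {
    mu_sd_m <- spec$traits$male[[v]]
    mu_sd_f <- spec$traits$female[[v]]
    draw <- ifelse(sex == "male",
                   rnorm(n, mu_sd_m[1], mu_sd_m[2]),
                   rnorm(n, mu_sd_f[1], mu_sd_f[2]))
    patients[[v]] <- draw
  }
  patients$sbp_sd <- pmax(patients$sbp_sd, 0.5)
  patients$smoking <- vapply(seq_len(n), function(i) {
    sample(SMOKING_LEVELS, 1,
           prob = spec$smoking_probs[[sex[i]]])
  }, character(1))
  # comorbidity onsets: present with the per-sex prevalence; onset age
  # uniform on [25, 65] so flags accumulate with entry age.  Treated
  # hypertension carries a nonzero default hazard coefficient, so its onset
  # precedes the first entry age: the at-entry flag then always matches the
  # covariate driving the patient's (time-invariant) log hazard.
  for (flag in names(COMORBIDITY_LABELS)) {
    prev_m <- spec$comorbidity_prev$male[[flag]]
    prev_f <- spec$comorbidity_prev$female[[flag]]
    present <- runif(n) < ifelse(sex == "male", prev_m, prev_f)
    hi <- if (flag == "treated_hypertension") 39 else 65
    onset <- ifelse(present, runif(n, 25, hi), NA_real_)
    patients[[paste0(flag, "_onset_age")]] <- onset
  }
  patients$true_lp <- true_linear_predictor(patients, spec)
  # prestratified risk group: rank-correlated with the true log hazard and
  # matching the per-sex marginal distribution exactly
  score <- patients$true_lp + rnorm(n, 0, 0.8)
  patients$prestrat_risk <- NA_character_
  for (s in c("male", "female")) {
    idx <- which(sex == s)
    if (!length(idx)) next
    probs <- spec$risk_group_probs[[s]]
    cuts <- quantile(score[idx], probs = cumsum(probs / sum(probs)))
    grp <- findInterval(score[idx], cuts[-length(cuts)], left.open = TRUE) + 1L
    patients$prestrat_risk[idx] <- RISK_LEVELS[grp]
  }
  # latent event age from the Weibull PH process anchored at age 40
  u <- runif(n)
  scale_d <- unname(spec$weibull_scale[sex])
  t_days <- scale_d * (-log(u) / exp(patients$true_lp))^(1 / spec$weibull_shape)
  patients$cvd_event_age <- 40 + t_days / 365
  cohort <- list(patients = patients,
                 measurements = generate_measurements(patients, spec),
                 spec = spec)
  class(cohort) <- "synth_cohort"
  cohort
}

# Standardized covariates entering the simulated log hazard.
true_linear_predictor <- function(patients, spec) {
  ref <- spec$lp_reference
  z <- function(v) (patients[[v]] - ref[[v]][1]) / ref[[v]][2]
  covars <- list(
    sbp = z("sbp"), bmi = z("bmi"), tchol_hdl_ratio = z("tchol_hdl_ratio"),
    townsend = z("townsend"),
    ever_smoker = as.numeric(patients$smoking != "nonsmoker"),
    treated_hypertension =
      as.numeric(!is.na(patients$treated_hypertension_onset_age))
  )
  lp <- numeric(nrow(patients))
  for (nm in names(spec$beta)) {
    if (spec$beta[[nm]] == 0) next
    if (is.null(covars[[nm]])) stop("unknown coefficient name: ", nm)
    lp <- lp + spec$beta[[nm]] * covars[[nm]]
  }
  lp
}

# One measurement per variable near each eligible entry (subject to the
# missingness rate) plus, occasionally, a short prior series that exercises
# the linear-regression imputation path.  Days are relative to age 40.
generate_measurements <- function(patients, spec) {
  vars <- names(spec$missingness)
  entries <- spec$entry_ages
  grid <- data.table::CJ(patient_id = patients$patient_id,
                         entry_age = entries, variable = vars,
                         sorted = FALSE)
  pat <- data.table::as.data.table(
    patients[, c("patient_id", "registration_age", vars)])
  long <- data.table::melt(pat, id.vars = c("patient_id", "registration_age"),
                           variable.name = "variable", value.name = "trait",
                           variable.factor = FALSE)
  grid <- merge(grid, long, by = c("patient_id", "variable"), sort = FALSE)
  grid <- grid[grid$entry_age >= grid$registration_age, ]
  m <- nrow(grid)
  if (m == 0) {
    return(data.table::data.table(patient_id = character(),
                                  variable = character(),
                                  day = integer(), value = numeric()))
  }
  entry_day <- (grid$entry_age - 40L) * 365L
  noise_sd <- unname(spec$measurement_noise[grid$variable])
  miss_p <- unname(spec$missingness[grid$variable])
  has_window <- runif(m) >= miss_p
  window_day <- entry_day + as.integer(round(runif(m, -183, 183)))
  window_val <- grid$trait + rnorm(m, 0, noise_sd)
  has_series <- runif(m) < 0.30
  out <- list(
    data.table::data.table(
      patient_id = grid$patient_id[has_window],
      variable = grid$variable[has_window],
      day = window_day[has_window],
      value = window_val[has_window])
  )
  if (any(has_series)) {
    k <- which(has_series)
    for (lag in c(600L, 400L, 200L)) {
      d <- entry_day[k] - lag + as.integer(round(runif(length(k), -30, 30)))
      out[[length(out) + 1]] <- data.table::data.table(
        patient_id = grid$patient_id[k],
        variable = grid$variable[k],
        day = d,
        value = grid$trait[k] + rnorm(length(k), 0, noise_sd[k]))
    }
  }
  meas <- data.table::rbindlist(out)
  data.table::setkeyv(meas, c("patient_id", "variable", "day"))
  meas[]
}

#' @export
print.synth_cohort <- function(x, ...) {
  ev <- mean(x$patients$cvd_event_age <= 85)
  cat(sprintf("synth_cohort: %d patients (preset '%s', seed %d), %d measurement rows\n",
              nrow(x$patients), x$spec$preset, x$spec$seed,
              nrow(x$measurements)))
  cat(sprintf("  latent event by age 85: %.1f%%\n", 100 * ev))
  invisible(x)
}

#' Simulate a fixed-horizon outcome for one patient episode
#'
#' Draws a time to event from the Weibull proportional-hazards process with
#' log hazard `x . beta`, conditioned on the patient being event-free at the
#' entry age (left truncation at the entry day).  Times beyond the horizon
#' are administratively censored; events inside the post-horizon grace
#' window keep a positive label with the time clipped to the horizon.
#'
#' @param history One row of the cohort's `patients` table (or any list with
#'   `true_lp`, `sex` and optionally `cvd_event_age`).
#' @param spec The [cohort_spec()].
#' @param entry_age Entry age in years (40-75 in 5-year steps).
#' @return List with `event` (0/1) and `tte_days` (integer in `[1, horizon]`).
#' @export
simulate_outcomes <- function(history, spec, entry_age) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$horizon_days < 1) stop("horizon must allow tte >= 1")
  history <- as.list(history)
  if (!is.null(history$cvd_event_age) && !is.na(history$cvd_event_age) &&
      history$cvd_event_age <= entry_age) {
    stop("entry must precede any recorded CVD event")
  }
  t0 <- (entry_age - 40) * 365
  scale_d <- unname(spec$weibull_scale[[history$sex]])
  u <- runif(1)
  # conditional inverse CDF given survival to t0
  t_abs <- scale_d * ((t0 / scale_d)^spec$weibull_shape -
                        log(u) / exp(history$true_lp))^(1 / spec$weibull_shape)
  label_episode(t_abs - t0, spec)
}

# Shared labelling rule: days from entry to the (latent) event.  Day counts
# are integral by definition, so the continuous age difference is rounded
# once before any comparison (protecting horizon/grace boundaries from
# floating-point noise).
label_episode <- function(days_to_event, spec) {
  h <- spec$horizon_days
  g <- spec$grace_days
  d <- if (is.na(days_to_event)) NA_integer_ else
    as.integer(round(days_to_event))
  if (is.na(d) || d > h + g) {
    list(event = 0L, tte_days = h)
  } else if (d > h) {
    list(event = 1L, tte_days = h)
  } else {
    list(event = 1L, tte_days = max(1L, d))
  }
}

#' Extract fixed-horizon prediction episodes for one patient
#'
#' One episode per eligible entry age: the patient must be registered by the
#' entry age and event-free at entry.  The episode is labelled positive when
#' the event falls within `horizon + grace` days of entry, with the recorded
#' time to event capped at the horizon; otherwise it is censored at the
#' horizon.
#'
#' @param history One row of the `patients` table (list or one-row
#'   data.frame) with `registration_age` and `cvd_event_age` (NA for none).
#' @param spec The [cohort_spec()].
#' @return data.frame with one row per episode (possibly zero rows):
#'   `patient_id`, `entry_age`, `event`, `tte_days`.
#' @export
extract_episodes <- function(history, spec) {
  history <- as.list(history)
  event_age <- history$cvd_event_age
  if (is.null(event_age)) event_age <- NA_real_
  reg_age <- if (is.null(history$registration_age)) 40 else
    history$registration_age
  eligible <- spec$entry_ages[spec$entry_ages >= reg_age]
  if (!is.na(event_age)) eligible <- eligible[eligible < event_age]
  if (!length(eligible)) {
    return(data.frame(patient_id = character(), entry_age = integer(),
                      event = integer(), tte_days = integer()))
  }
  rows <- lapply(eligible, function(a) {
    days <- if (is.na(event_age)) NA_real_ else (event_age - a) * 365
    lab <- label_episode(days, spec)
    data.frame(patient_id = history$patient_id, entry_age = as.integer(a),
               event = lab$event, tte_days = lab$tte_days)
  })
  do.call(rbind, rows)
}
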