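# Canonical category vocabularies used by both the simulator and the
# textualizer.  Display strings follow the narrative template conventions:
# lowercase except proper nouns, acronyms and the obesity class labels.

ETHNICITY_LEVELS <- c(
  "White", "Indian", "Pakistani", "Bangladeshi", "Chinese",
  "Other Asian", "Black Caribbean", "Black African", "Other ethnic group"
)

SMOKING_LEVELS <- c(
  "nonsmoker", "ex-smoker", "light smoker", "moderate smoker", "heavy smoker"
)

RISK_LEVELS <- c("low risk", "moderate risk", "high risk", "extreme high risk")

# Comorbidity flags in canonical row order; names are the column names used
# throughout, values are the display names inserted into the history sentence.
COMORBIDITY_LABELS <- c(
  diabetes             = "type 1/2 diabetes mellitus",
  ckd                  = "chronic kidney disease stage 3, 4, or 5",
  fh_chd               = "family history of coronary heart disease",
  af                   = "atrial fibrillation",
  ed                   = "erectile dysfunction",
  hiv                  = "HIV/AIDS",
  migraine             = "migraine",
  ra                   = "rheumatoid arthritis",
  sle                  = "systemic lupus erythematosus",
  smi                  = "severe mental illness",
  antipsychotic        = "antipsychotic",
  corticosteroid       = "corticosteroid",
  treated_hypertension = "treated hypertension"
)

CONTINUOUS_PREDICTORS <- c("age", "bmi", "sbp", "sbp_sd", "dbp",
                           "tchol_hdl_ratio", "townsend")

#' Age category for narrative rendering
#'
#' Maps an age in years onto the four narrative age classes used by the text
#' templates: below 45 is "young adult", 45-59 "middle-aged adult", 60-74
#' "young-old adult", and 75 or older "older adult".  Intervals are half-open
#' `[low, high)` so every in-range age maps to exactly one class.
#'
#' @param age Numeric vector of ages in years; must lie in the cohort range
#'   40 to 85.
#' @return Character vector of age categories.
#' @export
#' @examples
#' age_category(c(44, 52, 75))
age_category <- function(age) {
  stopifnot(is.numeric(age))
  if (any(!is.finite(age)) || any(age < 40) || any(age > 85)) {
    stop("age outside the cohort bounds [40, 85]")
  }
  cut_label(age, c(-Inf, 45, 60, 75, Inf),
            c("young adult", "middle-aged adult", "young-old adult",
              "older adult"))
}

#' BMI category for narrative rendering
#'
#' Maps body-mass index (kg/m^2) onto the six standard weight classes.
#' Intervals are half-open `[low, high)`: "normal weight" is `[18.5, 25.0)`,
#' "overweight (preobesity)" is `[25.0, 30.0)`, and so on, with
#' "Class 3 obesity (severe obesity)" for BMI of 40 and above.
#'
#' @param bmi Numeric vector of BMI values.
#' @param bounds Plausibility bounds; values outside raise a validation error.
#' @return Character vector of BMI categories.
#' @export
#' @examples
#' bmi_category(c(18.5, 27.45, 41))
bmi_category <- function(bmi, bounds = c(15, 70)) {
  stopifnot(is.numeric(bmi))
  if (any(!is.finite(bmi)) || any(bmi < bounds[1]) || any(bmi > bounds[2])) {
    stop("bmi outside plausibility bounds [", bounds[1], ", ", bounds[2], "]")
  }
  cut_label(bmi, c(-Inf, 18.5, 25, 30, 35, 40, Inf),
            c("underweight", "normal weight", "overweight (preobesity)",
              "Class 1 obesity", "Class 2 obesity",
              "Class 3 obesity (severe obesity)"))
}

#' Prestratified risk category
#'
#' Maps a 10-year risk percentage onto the four prestratified risk groups:
#' `[0, 5)`% low risk, `[5, 10)`% moderate risk, `[10, 20)`% high risk, and
#' 20% or above extreme high risk.
#'
#' @param risk_percent Numeric vector of risk percentages in `[0, 100]`.
#' @return Character vector of risk-group labels.
#' @export
#' @examples
#' risk_category(c(3.2, 10, 25))
risk_category <- function(risk_percent) {
  stopifnot(is.numeric(risk_percent))
  if (any(!is.finite(risk_percent)) || any(risk_percent < 0) ||
      any(risk_percent > 100)) {
    stop("risk_percent must lie in [0, 100]")
  }
  cut_label(risk_percent, c(-Inf, 5, 10, 20, Inf), RISK_LEVELS)
}

cut_label <- function(x, breaks, labels) {
  labels[findInterval(x, breaks[-1], left.open = FALSE) + 1L]
}

#' Compose the clinical narrative for an episode
#'
#' Deterministically renders one prediction episode into the narrative string
#' consumed by the text encoder.  Sentence order is fixed: (1) demographics
#' (age class, BMI class, ethnicity), (2) smoking status, (3) prestratified
#' risk, (4) comorbidity history listing the flagged conditions
#' comma-separated in canonical order; the history sentence is omitted when
#' no flags are set.  Numeric-only predictors (blood pressures, lipid ratio,
#' deprivation score) do not appear in the text.
#'
#' @param episode A list or one-row data.frame with fields `entry_age`,
#'   `bmi`, `ethnicity`, `smoking`, `prestrat_risk` (one of the four risk
#'   labels) and the 13 comorbidity flag columns named as in
#'   [COMORBIDITY_LABELS].
#' @return A character scalar.
#' @export
#' @examples
#' ep <- list(entry_age = 52, bmi = 31, ethnicity = "Indian",
#'            smoking = "ex-smoker", prestrat_risk = "moderate risk",
#'            migraine = 1, treated_hypertension = 1)
#' compose_narrative(ep)
compose_narrative <- function(episode) {
  ep <- as.list(episode)
  if (!ep$ethnicity %in% ETHNICITY_LEVELS) {
    stop("unknown ethnicity: ", ep$ethnicity)
  }
  if (!ep$smoking %in% SMOKING_LEVELS) {
    stop("unknown smoking status: ", ep$smoking)
  }
  if (!ep$prestrat_risk %in% RISK_LEVELS) {
    stop("unknown risk group: ", ep$prestrat_risk)
  }
  s1 <- sprintf("The patient is a %s with a BMI classified as %s and is of %s ethnicity.",
                age_category(ep$entry_age), bmi_category(ep$bmi), ep$ethnicity)
  s2 <- sprintf("The patient is a %s.", ep$smoking)
  s3 <- sprintf("Pre-stratified risk indicating a %s.", ep$prestrat_risk)
  flags <- vapply(names(COMORBIDITY_LABELS), function(nm) {
    v <- ep[[nm]]
    !is.null(v) && !is.na(v) && v == 1
  }, logical(1))
  parts <- c(s1, s2, s3)
  if (any(flags)) {
    s4 <- sprintf("The patient has a history of %s.",
                  paste(COMORBIDITY_LABELS[flags], collapse = ", "))
    parts <- c(parts, s4)
  }
  paste(parts, collapse = " ")
}

#' Compose narratives for a table of episodes
#'
#' Vectorized wrapper around [compose_narrative()]; preserves row order.
#'
#' @param episodes data.frame of episodes, one per row.
#' @return Character vector, one narrative per row.
#' @export
compose_narratives <- function(episodes) {
  episodes <- as.data.frame(episodes)
  vapply(seq_len(nrow(episodes)),
         function(i) compose_narrative(episodes[i, , drop = FALSE]),
         character(1))
}
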