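# Episode-table construction from a synthetic cohort, and the prepared
# dataset bundle consumed by the trainer.

#' Build the full episode table for a cohort
#'
#' Vectorized application of the episode extraction rules to every patient:
#' eligibility (registered and event-free at entry), outcome labelling with
#' the post-horizon grace window, comorbidity flags at entry, and windowed
#' resolution of the continuous predictors (nearest measurement within
#' +/-183 days, then linear-regression imputation from at least 3 prior
#' measurements within 730 days, else `NA`).
#'
#' @param cohort A `synth_cohort` from [generate_cohort()].
#' @return data.frame with one row per episode: identifiers, predictors,
#'   `event`, `tte_days`, subgroup tags and the simulation ground truth
#'   (`true_lp`).
#' @export
build_episode_table <- function(cohort) {
  stopifnot(inherits(cohort, "synth_cohort"))
  spec <- cohort$spec
  pat <- data.table::as.data.table(cohort$patients)
  grid <- pat[, .(entry_age = spec$entry_ages), by = patient_id]
  grid <- merge(grid, pat, by = "patient_id", sort = FALSE)
  grid <- grid[grid$entry_age >= grid$registration_age &
                 (is.na(grid$cvd_event_age) |
                    grid$cvd_event_age > grid$entry_age), ]
  if (nrow(grid) == 0) stop("cohort yields no eligible episodes")
  days <- as.integer(round((grid$cvd_event_age - grid$entry_age) * 365))
  h <- spec$horizon_days
  g <- spec$grace_days
  event <- as.integer(!is.na(days) & days <= h + g)
  tte <- ifelse(event == 1, pmax(1L, pmin(h, days)), h)
  eps <- data.frame(
    patient_id = grid$patient_id,
    entry_age = as.integer(grid$entry_age),
    sex = grid$sex,
    ethnicity = grid$ethnicity,
    smoking = grid$smoking,
    prestrat_risk = grid$prestrat_risk,
    townsend = grid$townsend,
    event = event,
    tte_days = as.integer(tte),
    true_lp = grid$true_lp,
    stringsAsFactors = FALSE
  )
  eps$age <- as.numeric(eps$entry_age)
  for (flag in names(COMORBIDITY_LABELS)) {
    onset <- grid[[paste0(flag, "_onset_age")]]
    eps[[flag]] <- as.integer(!is.na(onset) & onset < grid$entry_age)
  }
  resolved <- resolve_continuous(eps, cohort$measurements, spec)
  eps <- cbind(eps, resolved)
  eps$deprivation_quantile <- deprivation_quantile(eps$townsend, 5)
  eps
}

# Vectorized windowed resolution + OLS imputation for all episodes at once.
# One "cell" is an (episode, variable) pair; resolution follows the same
# rules as resolve_windowed()/impute_linear() and is oracle-checked against
# them in the test suite.
resolve_continuous <- function(eps, meas, spec, window = 183,
                               span_days = 730, min_points = 3) {
  vars <- names(spec$missingness)
  n <- nrow(eps)
  out <- as.data.frame(matrix(NA_real_, n, length(vars)))
  names(out) <- vars
  if (nrow(meas) == 0) return(out)
  cells <- data.table::CJ(epid = seq_len(n), variable = vars, sorted = FALSE)
  cells$cell <- seq_len(nrow(cells))
  cells$patient_id <- eps$patient_id[cells$epid]
  cells$entry_day <- (eps$entry_age[cells$epid] - 40L) * 365L
  m <- data.table::copy(meas)
  m$mday <- m$day
  # nearest measurement to the entry day, any distance
  near <- m[cells, on = c("patient_id", "variable", day = "entry_day"),
            roll = "nearest"]
  near$dist <- abs(near$mday - near$day)
  hit <- !is.na(near$value) & near$dist <= window
  set_cells <- function(cell_ids, values) {
    ep <- cells$epid[cell_ids]
    va <- cells$variable[cell_ids]
    for (v in unique(va)) {
      sel <- va == v
      out[[v]][ep[sel]] <<- values[sel]
    }
  }
  if (any(hit)) set_cells(near$cell[hit], near$value[hit])
  # imputation for unresolved cells: OLS over prior points within the span
  todo <- near[!hit, c("cell", "patient_id", "variable", "day")]
  if (nrow(todo) > 0) {
    todo$lo <- todo$day - span_days
    prior <- m[todo,
               .(cell = i.cell, entry_day = i.day, pday = x.mday,
                 value = x.value),
               on = c("patient_id", "variable", "mday < day", "mday >= lo"),
               nomatch = NULL]
    if (nrow(prior) > 0) {
      # average duplicate days, then closed-form OLS per cell
      prior <- prior[, .(value = mean(value)),
                     by = .(cell, entry_day, pday)]
      fit <- prior[, {
        if (.N < min_points) {
          list(pred = NA_real_)
        } else {
          xc <- pday - mean(pday)
          sxx <- sum(xc^2)
          slope <- if (sxx == 0) 0 else sum(xc * value) / sxx
          list(pred = mean(value) + slope * (entry_day[1] - mean(pday)))
        }
      }, by = cell]
      ok <- !is.na(fit$pred)
      if (any(ok)) set_cells(fit$cell[ok], fit$pred[ok])
    }
  }
  out
}

#' Prepare a cohort for training
#'
#' Full preprocessing pipeline: episode table, quality control, narrative
#' rendering, median fill of any continuous predictors that remain
#' unresolved after windowing and imputation, stratified splitting (with
#' the patient-group constraint by default), min-max scaling fitted on the
#' training partition, and class weights from the training labels.
#'
#' @param cohort A `synth_cohort`, or an episode data.frame from
#'   [build_episode_table()] / [read_cohort()].
#' @param ratios Train/val/test ratios (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed for the split.
#' @param qc_bounds Plausibility bounds passed to [qc_filter()].
#' @param weight_beta,weight_r_ref Class-weight scaling parameters, see
#'   [class_weights()].
#' @return Object of class `prepared_data`: list with `episodes` (QC-passed,
#'   scaled features in `features`), `narratives`, `split`, `scaler`,
#'   `class_weights`, `qc_log`, `feature_names`.
#' @export
prepare_dataset <- function(cohort, ratios = c(0.70, 0.15, 0.15), seed = 1,
                            qc_bounds = NULL, weight_beta = 0,
                            weight_r_ref = 0.08) {
  group_split <- TRUE
  if (inherits(cohort, "synth_cohort")) {
    group_split <- cohort$spec$group_split_by_patient
    eps <- build_episode_table(cohort)
  } else {
    eps <- as.data.frame(cohort)
  }
  qc <- if (is.null(qc_bounds)) qc_filter(eps) else
    qc_filter(eps, bounds = qc_bounds)
  eps <- qc$kept
  rownames(eps) <- NULL
  split <- split_dataset(eps, ratios = ratios, seed = seed,
                         group = if (group_split) eps$patient_id else NULL)
  train_idx <- split == "train"
  # median fill (training medians) for continuous predictors still NA
  cont <- intersect(CONTINUOUS_PREDICTORS, names(eps))
  for (v in cont) {
    med <- median(eps[[v]][train_idx], na.rm = TRUE)
    eps[[v]][is.na(eps[[v]])] <- med
  }
  narratives <- compose_narratives(eps)
  scaler <- fit_scaler(eps[train_idx, , drop = FALSE], vars = cont)
  scaled <- transform_scale(scaler, eps[, cont, drop = FALSE])
  # one-hot encoding for the categorical predictors of the structured branch
  onehot <- function(x, levels, prefix) {
    m <- outer(x, levels, `==`) * 1
    colnames(m) <- paste0(prefix, "_", gsub("[^a-z0-9]+", "_",
                                            tolower(levels)))
    m
  }
  feat <- cbind(
    as.matrix(scaled),
    onehot(eps$ethnicity, ETHNICITY_LEVELS, "eth"),
    onehot(eps$smoking, SMOKING_LEVELS, "smok"),
    onehot(eps$prestrat_risk, RISK_LEVELS, "risk"),
    as.matrix(eps[, names(COMORBIDITY_LABELS)]),
    sex_male = as.numeric(eps$sex == "male")
  )
  cw <- class_weights(eps$event[train_idx], beta = weight_beta,
                      r_ref = weight_r_ref)
  out <- list(episodes = eps, features = feat,
              feature_names = colnames(feat), narratives = narratives,
              split = split, scaler = scaler, class_weights = cw,
              qc_log = qc$log)
  class(out) <- "prepared_data"
  out
}

#' @export
print.prepared_data <- function(x, ...) {
  cat(sprintf("prepared_data: %d episodes (%d features), split %s\n",
              nrow(x$episodes), ncol(x$features),
              paste(table(x$split)[c("train", "val", "test")],
                    collapse = "/")))
  cat(sprintf("  event rate %.1f%%; class weights %.2f / %.2f\n",
              100 * mean(x$episodes$event), x$class_weights["w_neg"],
              x$class_weights["w_pos"]))
  invisible(x)
}

#' Write a cohort's episodes to CSV with a generator sidecar
#'
#' One episode per row; the JSON sidecar records the ground-truth
#' coefficients and generator settings.
#'
#' @param cohort A `synth_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eps <- build_episode_table(cohort)
  csv <- file.path(dir, "episodes.csv")
  json <- file.path(dir, "generator.json")
  utils::write.csv(eps, csv, row.names = FALSE)
  spec <- cohort$spec
  jsonlite::write_json(list(
    preset = spec$preset, n_patients = spec$n_patients, seed = spec$seed,
    beta = as.list(spec$beta), weibull_shape = spec$weibull_shape,
    weibull_scale = as.list(spec$weibull_scale),
    baseline_event_rate = as.list(spec$baseline_event_rate),
    horizon_days = spec$horizon_days, grace_days = spec$grace_days,
    ethnicity_probs = as.list(spec$ethnicity_probs)
  ), json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}

#' Read an episode table written by [write_cohort()]
#'
#' @param dir Directory holding `episodes.csv` (and optionally
#'   `generator.json`, attached as the `generator` attribute).
#' @return data.frame of episodes.
#' @export
read_cohort <- function(dir) {
  eps <- utils::read.csv(file.path(dir, "episodes.csv"),
                         stringsAsFactors = FALSE)
  sidecar <- file.path(dir, "generator.json")
  if (file.exists(sidecar)) {
    attr(eps, "generator") <- jsonlite::read_json(sidecar,
                                                  simplifyVector = TRUE)
  }
  eps
}
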