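# Windowed predictor resolution, imputation, QC, scaling, splitting and
# class-weight computation.

#' Resolve a predictor value at an entry date from a patient's records
#'
#' Applies the windowing rules used at episode construction: the record
#' nearest the entry day within a +/-183-day window wins; in the absence of
#' an in-window record, smoking status falls back to the most recent prior
#' record, and medication flags fall back to any prior prescription (flag 1
#' if one exists, else 0).  Comorbidity flags are 1 iff the recorded onset
#' precedes entry.  Absence of records is a value (no occurrence), not
#' missing data, for the fallback classes.
#'
#' @param records data.frame with columns `day` and `value` for one patient
#'   and one variable (days relative to the same anchor as `entry_day`).
#' @param variable Variable name; behaviour switches on `kind`.
#' @param entry_day Integer entry day.
#' @param kind One of `"measurement"` (continuous, window only),
#'   `"status"` (e.g. smoking: window, then most recent prior),
#'   `"medication"` (window, then any prior record => 1 else 0),
#'   `"onset"` (records are onset days; 1 iff any onset < entry).
#' @param window Half-width of the resolution window in days (default 183).
#' @return The resolved value, or `NA` when unresolvable (continuous and
#'   status kinds only).
#' @export
resolve_windowed <- function(records, variable, entry_day,
                             kind = c("measurement", "status", "medication",
                                      "onset"),
                             window = 183) {
  kind <- match.arg(kind)
  if (kind == "onset") {
    return(as.integer(nrow(records) > 0 && any(records$day < entry_day)))
  }
  if (nrow(records) > 0) {
    d <- abs(records$day - entry_day)
    in_window <- which(d <= window)
    if (length(in_window)) {
      best <- in_window[which.min(d[in_window])]
      return(if (kind == "medication") 1L else records$value[best])
    }
  }
  prior <- records[records$day < entry_day, , drop = FALSE]
  if (kind == "medication") return(as.integer(nrow(prior) > 0))
  if (kind == "status" && nrow(prior) > 0) {
    return(prior$value[which.max(prior$day)])
  }
  NA
}

#' Linear-regression imputation from prior measurements
#'
#' Ordinary-least-squares line through the qualifying prior points (at
#' least 3 measurements strictly before the entry day and within a 730-day
#' look-back), evaluated at the entry day.  Duplicate days with conflicting
#' values are averaged before the fit.  Returns `NA` when fewer than 3
#' qualifying points exist.
#'
#' @param points data.frame with columns `day` and `value`.
#' @param entry_day Integer entry day.
#' @param span_days Look-back span (default 730).
#' @param min_points Minimum qualifying points (default 3).
#' @return Imputed value or `NA`.
#' @export
#' @examples
#' impute_linear(data.frame(day = c(-600, -400, -200),
#'                          value = c(120, 125, 130)), 0)  # 135
impute_linear <- function(points, entry_day, span_days = 730,
                          min_points = 3) {
  q <- points[points$day < entry_day & points$day >= entry_day - span_days, ,
              drop = FALSE]
  if (nrow(q) == 0) return(NA_real_)
  if (anyDuplicated(q$day)) {
    agg <- tapply(q$value, q$day, mean)
    q <- data.frame(day = as.numeric(names(agg)), value = as.numeric(agg))
  }
  if (nrow(q) < min_points) return(NA_real_)
  x <- q$day - mean(q$day)
  sxx <- sum(x^2)
  slope <- if (sxx == 0) 0 else sum(x * q$value) / sxx
  mean(q$value) + slope * (entry_day - mean(q$day))
}

#' Quality-control filter on continuous predictors
#'
#' Removes episodes with any continuous value outside the configured
#' plausibility bounds and logs each rejection.
#'
#' @param episodes data.frame of episodes.
#' @param bounds Named list of `c(low, high)` bounds per variable; defaults
#'   cover systolic/diastolic blood pressure, BMI and the lipid ratio.
#' @return List with `kept` (episodes passing QC) and `log` (data.frame of
#'   `row`, `variable`, `value` for each rejection).
#' @export
qc_filter <- function(episodes,
                      bounds = list(sbp = c(60, 250), dbp = c(30, 150),
                                    bmi = c(15, 70),
                                    tchol_hdl_ratio = c(1, 12))) {
  episodes <- as.data.frame(episodes)
  bad <- rep(FALSE, nrow(episodes))
  log_rows <- list()
  for (v in intersect(names(bounds), names(episodes))) {
    x <- episodes[[v]]
    out <- !is.na(x) & (x < bounds[[v]][1] | x > bounds[[v]][2])
    if (any(out)) {
      log_rows[[v]] <- data.frame(row = which(out), variable = v,
                                  value = x[out])
      bad <- bad | out
    }
  }
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(row = integer(), variable = character(), value = numeric())
  rownames(log) <- NULL
  list(kept = episodes[!bad, , drop = FALSE], log = log)
}

#' Fit a min-max scaler on the training partition
#'
#' @param train data.frame of training episodes.
#' @param vars Variables to scale (default: the continuous predictors
#'   present in `train`).
#' @return Object of class `scaler_state` holding per-feature `(min, max)`.
#' @export
fit_scaler <- function(train, vars = NULL) {
  if (is.null(vars)) vars <- intersect(CONTINUOUS_PREDICTORS, names(train))
  state <- lapply(vars, function(v) {
    x <- train[[v]]
    c(min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
  })
  names(state) <- vars
  structure(list(ranges = state), class = "scaler_state")
}

#' Min-max transform episodes with a fitted scaler
#'
#' `x' = (x - min) / (max - min)` with the training-partition range;
#' constant features map to 0 and out-of-range values (non-training
#' partitions) are clipped to `[0, 1]`.
#'
#' @param state A `scaler_state` from [fit_scaler()].
#' @param episodes data.frame to transform.
#' @return The data.frame with scaled columns.
#' @export
transform_scale <- function(state, episodes) {
  if (!inherits(state, "scaler_state")) {
    stop("state error: scaler must be fitted with fit_scaler() first")
  }
  for (v in names(state$ranges)) {
    r <- state$ranges[[v]]
    span <- r["max"] - r["min"]
    x <- episodes[[v]]
    episodes[[v]] <- if (span == 0) ifelse(is.na(x), NA_real_, 0) else
      pmin(pmax((x - r["min"]) / span, 0), 1)
  }
  episodes
}

#' Invert the min-max transform (training-partition values only)
#'
#' @inheritParams transform_scale
#' @export
inverse_scale <- function(state, episodes) {
  for (v in names(state$ranges)) {
    r <- state$ranges[[v]]
    episodes[[v]] <- episodes[[v]] * (r["max"] - r["min"]) + r["min"]
  }
  episodes
}

# largest-remainder allocation of n items to partitions with given ratios;
# remainder ties are broken by a rotating preference so that equal-ratio
# partitions (e.g. val/test at 15:15) do not drift systematically when the
# allocation repeats across strata
allocate_counts <- function(n, ratios, rotate = 0) {
  raw <- n * ratios / sum(ratios)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    rv <- round(raw - base, 12)
    ord <- integer(0)
    for (u in sort(unique(rv), decreasing = TRUE)) {
      ties <- which(rv == u)
      if (length(ties) > 1) {
        sh <- rotate %% length(ties)
        ties <- c(ties[seq_len(length(ties) - sh) + sh],
                  ties[seq_len(sh)])
      }
      ord <- c(ord, ties)
    }
    extra <- ord[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  base
}

#' Stratified train/validation/test split
#'
#' Deterministic per seed; stratified by event label and sex.  With the
#' patient-group constraint (the default when `group` is supplied), all of
#' a patient's episodes stay in one partition and stratification operates
#' at the patient level (any-event x sex), making event rates approximate
#' rather than exact.
#'
#' @param episodes data.frame with `event` and `sex` columns.
#' @param ratios Length-3 numeric summing to 1 (train, val, test); default
#'   `c(0.70, 0.15, 0.15)`.
#' @param seed Integer seed.
#' @param group Optional grouping vector (patient ids); `NULL` splits
#'   episodes independently.
#' @return Character vector of partition labels (`"train"`, `"val"`,
#'   `"test"`) aligned with the rows of `episodes`.
#' @export
split_dataset <- function(episodes, ratios = c(0.70, 0.15, 0.15), seed = 1,
                          group = NULL) {
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  labels <- c("train", "val", "test")
  set.seed(seed)
  n <- nrow(episodes)
  out <- character(n)
  if (is.null(group)) {
    stratum <- paste(episodes$event, episodes$sex)
    for (si in seq_along(unique(stratum))) {
      s <- unique(stratum)[si]
      idx <- which(stratum == s)
      if (length(idx) < length(labels)) {
        warning("stratum '", s, "' smaller than the number of partitions; ",
                "best-effort assignment")
      }
      idx <- idx[sample.int(length(idx))]
      counts <- allocate_counts(length(idx), ratios, rotate = si - 1)
      out[idx] <- rep(labels, counts)
    }
  } else {
    pat <- data.frame(group = group, event = episodes$event,
                      sex = episodes$sex)
    agg <- stats::aggregate(event ~ group + sex, data = pat, FUN = max)
    stratum <- paste(agg$event, agg$sex)
    assign_pat <- character(nrow(agg))
    for (si in seq_along(unique(stratum))) {
      s <- unique(stratum)[si]
      idx <- which(stratum == s)
      idx <- idx[sample.int(length(idx))]
      counts <- allocate_counts(length(idx), ratios, rotate = si - 1)
      assign_pat[idx] <- rep(labels, counts)
    }
    out <- assign_pat[match(group, agg$group)]
  }
  out
}

#' Stratified k-fold assignment
#'
#' @inheritParams split_dataset
#' @param k Number of folds, at least 2.
#' @return Integer fold labels `1..k`.
#' @export
split_kfold <- function(episodes, k = 10, seed = 1, group = NULL) {
  if (k < 2) stop("k must be >= 2")
  set.seed(seed)
  n <- nrow(episodes)
  out <- integer(n)
  if (is.null(group)) {
    stratum <- paste(episodes$event, episodes$sex)
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      idx <- idx[sample.int(length(idx))]
      out[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    pat <- data.frame(group = group, event = episodes$event,
                      sex = episodes$sex)
    agg <- stats::aggregate(event ~ group + sex, data = pat, FUN = max)
    stratum <- paste(agg$event, agg$sex)
    fold_pat <- integer(nrow(agg))
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      idx <- idx[sample.int(length(idx))]
      fold_pat[idx] <- rep_len(seq_len(k), length(idx))
    }
    out <- fold_pat[match(group, agg$group)]
  }
  out
}

#' Dynamically scaled class weights
#'
#' Standard balanced class weights `n / (2 n_c)`, with the positive-class
#' weight additionally scaled by `(r_ref / r_obs)^beta` (the observed event
#' rate relative to a reference rate), then normalized so the
#' frequency-weighted mean weight is 1.  `beta = 0` (the default) is the
#' pure balanced scheme.
#'
#' @param labels Binary training labels; both classes must be present.
#' @param beta Event-rate scaling exponent (default 0).
#' @param r_ref Reference event rate (default 0.08).
#' @return Named vector `c(w_neg, w_pos)`.
#' @export
#' @examples
#' class_weights(c(rep(0, 90), rep(1, 10)))  # ratio 9
class_weights <- function(labels, beta = 0, r_ref = 0.08) {
  n <- length(labels)
  n_pos <- sum(labels == 1)
  n_neg <- n - n_pos
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  w_neg <- n / (2 * n_neg)
  w_pos <- n / (2 * n_pos)
  r_obs <- n_pos / n
  w_pos <- w_pos * (r_ref / r_obs)^beta
  norm <- (n_neg * w_neg + n_pos * w_pos) / n
  c(w_neg = w_neg / norm, w_pos = w_pos / norm)
}
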