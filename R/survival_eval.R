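# Discrimination, calibration, thresholded classification and survival
# stratification metrics for 10-year risk predictions.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with half credit for tied scores.
#'
#' @param scores Predicted scores or probabilities.
#' @param labels Binary labels (0/1); both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))  # 0.75
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  y <- as.integer(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Percentile bootstrap confidence interval for the AUROC
#'
#' @inheritParams auroc
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(lo, hi)`.
#' @export
auroc_ci <- function(scores, labels, B = 1000, seed = 1, level = 0.95) {
  set.seed(seed)
  n <- length(scores)
  boot <- replicate(B, {
    b <- sample.int(n, replace = TRUE)
    if (length(unique(labels[b])) < 2) NA_real_ else auroc(scores[b], labels[b])
  })
  boot <- boot[!is.na(boot)]
  a <- (1 - level) / 2
  stats::setNames(unname(quantile(boot, c(a, 1 - a))), c("lo", "hi"))
}

#' Harrell's concordance index
#'
#' Probability that, among comparable pairs (pairs orderable under
#' censoring: the earlier time must be an observed event, with strictly
#' unequal times), the subject with the earlier event carries the higher
#' predicted risk; tied risk scores receive half credit.  Tied-time pairs
#' are not comparable under this convention (the variant
#' `survival::concordance` computes additionally orders an event before a
#' censoring at the same time; the two agree whenever times are untied).
#'
#' @param h Predicted risk scores (higher = higher risk), e.g. log hazards.
#' @param t Times to event or censoring.
#' @param e Event indicators (1 = event).
#' @return Concordance index in `[0, 1]`.
#' @export
#' @examples
#' c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 0))  # 1
c_index <- function(h, t, e) {
  stopifnot(length(h) == length(t), length(t) == length(e))
  n <- length(h)
  num <- 0
  den <- 0
  # block over the reference events to keep memory linear in n per pass
  ev <- which(e == 1)
  if (length(ev)) {
    blocks <- split(ev, ceiling(seq_along(ev) / 512))
    for (b in blocks) {
      later <- outer(t[b], t, `<`)          # strictly later times only
      den <- den + sum(later)
      hb <- h[b]
      num <- num + sum(later * (outer(hb, h, `>`) + 0.5 * outer(hb, h, `==`)))
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Brier score at the fixed horizon
#'
#' Mean squared difference between predicted probabilities and the binary
#' 10-year outcome.  Censoring here is administrative at exactly the
#' horizon, so no inverse-probability-of-censoring weighting is applied by
#' default; `ipcw = TRUE` weights by the Kaplan-Meier censoring distribution
#' for general censoring patterns.
#'
#' @param p Predicted probabilities in `[0, 1]`.
#' @param y Binary outcome labels.
#' @param ipcw Apply inverse-probability-of-censoring weights (requires
#'   `t` and `e`).
#' @param t,e Times and event indicators, only used when `ipcw = TRUE`.
#' @return Scalar Brier score.
#' @export
brier <- function(p, y, ipcw = FALSE, t = NULL, e = NULL) {
  stopifnot(all(p >= 0 & p <= 1))
  if (!ipcw) return(mean((p - y)^2))
  stopifnot(!is.null(t), !is.null(e))
  cens_fit <- survival::survfit(survival::Surv(t, 1 - e) ~ 1)
  G <- stats::stepfun(cens_fit$time, c(1, cens_fit$surv))
  w <- ifelse(y == 1, 1 / pmax(G(t), 1e-8), 1 / pmax(G(max(t)), 1e-8))
  sum(w * (p - y)^2) / sum(w)
}

#' Isotonic probability calibration
#'
#' Fits a monotone non-decreasing mapping from predicted probabilities to
#' observed event rates by pool-adjacent-violators (via `stats::isoreg`),
#' typically on the validation partition, for application to test-set
#' predictions.
#'
#' @param p Predicted probabilities (calibration partition).
#' @param y Binary outcomes (calibration partition).
#' @return An object of class `iso_calibrator`; use [predict.iso_calibrator()]
#'   to map new probabilities.
#' @export
calibrate_isotonic <- function(p, y) {
  stopifnot(length(p) == length(y))
  ord <- order(p)
  fit <- stats::isoreg(p[ord], y[ord])
  # collapse to unique knots (tied inputs inside one PAVA block share a value)
  knots <- tapply(fit$yf, fit$x, mean)
  obj <- list(x = as.numeric(names(knots)), y = as.numeric(knots))
  class(obj) <- "iso_calibrator"
  obj
}

#' @rdname calibrate_isotonic
#' @param object An `iso_calibrator`.
#' @param newdata Probabilities to calibrate.
#' @param ... Unused.
#' @export
predict.iso_calibrator <- function(object, newdata, ...) {
  if (length(object$x) == 1) return(rep(object$y, length(newdata)))
  stats::approx(object$x, object$y, xout = newdata, rule = 2)$y
}

#' Calibration table by predicted-risk deciles
#'
#' Partitions observations into deciles of predicted risk and reports, per
#' bin, the number of observations, mean predicted risk and observed event
#' rate.
#'
#' @inheritParams brier
#' @return data.frame with columns `decile`, `n`, `mean_pred`, `obs_rate`.
#' @export
decile_table <- function(p, y) {
  breaks <- unique(quantile(p, probs = seq(0, 1, by = 0.1)))
  if (length(breaks) < 3) {
    bin <- rep(1L, length(p))
  } else {
    bin <- cut(p, breaks = breaks, labels = FALSE, include.lowest = TRUE)
  }
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    data.frame(decile = b, n = sum(idx), mean_pred = mean(p[idx]),
               obs_rate = mean(y[idx]))
  }))
  rownames(out) <- NULL
  out
}

#' Classification metrics at a probability threshold
#'
#' @inheritParams brier
#' @param threshold Decision threshold in `[0, 1]`; predictions at or above
#'   it are classified positive.
#' @return Named vector with `accuracy`, `recall`, `specificity`.
#' @export
classify_at_threshold <- function(p, y, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  pred <- as.integer(p >= threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  c(accuracy = (tp + tn) / length(y),
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Decision threshold maximizing Youden's J
#'
#' Scans the unique predicted probabilities and returns the threshold
#' maximizing sensitivity + specificity - 1; ties resolve to the smallest
#' threshold.
#'
#' @inheritParams brier
#' @return Scalar threshold.
#' @export
youden_threshold <- function(p, y) {
  cand <- sort(unique(p))
  j <- vapply(cand, function(th) {
    m <- classify_at_threshold(p, y, th)
    m["recall"] + m["specificity"] - 1
  }, numeric(1))
  cand[which.max(j)]
}

#' Kaplan-Meier product-limit curves by risk group
#'
#' Product-limit survival estimates with Greenwood standard errors per
#' group.  Rows after the last time point with at least `min_at_risk`
#' individuals at risk are flagged as suppressed (the convention used when
#' plotting).
#'
#' @param t Times.
#' @param e Event indicators.
#' @param group Group labels (e.g. "high"/"low" predicted risk).
#' @param min_at_risk At-risk count below which curve segments are
#'   suppressed (default 10).
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`, `std_err`, `lower`, `upper`, `suppressed`.
#' @export
km_curve <- function(t, e, group, min_at_risk = 10) {
  stopifnot(all(t > 0))
  group <- as.character(group)
  if (any(table(group) == 0) || length(group) == 0) stop("empty group")
  out <- do.call(rbind, lapply(sort(unique(group)), function(g) {
    idx <- group == g
    fit <- survival::survfit(survival::Surv(t[idx], e[idx]) ~ 1,
                             conf.type = "log")
    data.frame(group = g, time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, surv = fit$surv,
               std_err = fit$surv * fit$std.err,
               lower = fit$lower, upper = fit$upper,
               suppressed = fit$n.risk < min_at_risk)
  }))
  rownames(out) <- NULL
  out
}

#' Log-rank test between risk groups
#'
#' @inheritParams km_curve
#' @return List with `chisq`, `df` and `p`.
#' @export
logrank <- function(t, e, group) {
  group <- as.character(group)
  if (length(unique(group)) < 2) stop("log-rank requires at least two groups")
  fit <- survival::survdiff(survival::Surv(t, e) ~ group)
  df <- length(fit$n) - 1
  list(chisq = fit$chisq, df = df,
       p = stats::pchisq(fit$chisq, df = df, lower.tail = FALSE))
}

#' Sex-specific high/low risk stratification
#'
#' Classifies calibrated 10-year risk probabilities into high and low risk
#' groups using sex-specific thresholds: 40% or greater for men and 34% or
#' greater for women by default (both inclusive).
#'
#' @param p Calibrated probabilities.
#' @param sex Character vector, `"male"` or `"female"`.
#' @param thresholds Named numeric vector with elements `male` and `female`.
#' @return Character vector `"high"`/`"low"`.
#' @export
#' @examples
#' stratify_risk(c(0.41, 0.34, 0.33), c("male", "female", "female"))
stratify_risk <- function(p, sex, thresholds = c(male = 0.40, female = 0.34)) {
  if (!all(sex %in% c("male", "female"))) stop("unknown sex code")
  th <- unname(thresholds[sex])
  ifelse(p >= th, "high", "low")
}

#' Full metric report for a set of predictions
#'
#' Assembles discrimination, calibration, thresholded classification and
#' survival stratification metrics into one report.  The isotonic
#' calibrator and the decision threshold are fitted on the validation
#' predictions and applied to the test predictions.
#'
#' @param test List with elements `prob`, `hazard`, `t`, `e`, `sex`.
#' @param val List with the same elements, used to fit the calibrator and
#'   the Youden threshold.
#' @param B Bootstrap resamples for CIs (default 1000).
#' @param seed Integer seed.
#' @param threshold Optional fixed decision threshold; defaults to Youden's
#'   J on the validation partition.
#' @return Object of class `metric_report` (a list).
#' @export
metric_report <- function(test, val, B = 1000, seed = 1, threshold = NULL) {
  calib <- calibrate_isotonic(val$prob, val$e)
  p_cal <- predict(calib, test$prob)
  if (is.null(threshold)) threshold <- youden_threshold(val$prob, val$e)
  cls <- classify_at_threshold(test$prob, test$e, threshold)
  groups <- stratify_risk(p_cal, test$sex)
  km <- km_curve(test$t, test$e, groups)
  lr <- if (length(unique(groups)) >= 2) logrank(test$t, test$e, groups) else NULL
  rep <- list(
    auroc = auroc(test$prob, test$e),
    auroc_ci = auroc_ci(test$prob, test$e, B = B, seed = seed),
    c_index = c_index(test$hazard, test$t, test$e),
    brier = brier(test$prob, test$e),
    brier_calibrated = brier(p_cal, test$e),
    threshold = threshold,
    accuracy = unname(cls["accuracy"]),
    recall = unname(cls["recall"]),
    specificity = unname(cls["specificity"]),
    calibration = decile_table(p_cal, test$e),
    km = km,
    logrank = lr,
    risk_groups = table(groups)
  )
  class(rep) <- "metric_report"
  rep
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Metric report\n")
  cat(sprintf("  AUROC: %.3f (95%% CI %.3f-%.3f)\n",
              x$auroc, x$auroc_ci["lo"], x$auroc_ci["hi"]))
  cat(sprintf("  C-index: %.3f\n", x$c_index))
  cat(sprintf("  Brier: %.3f (calibrated %.3f)\n", x$brier,
              x$brier_calibrated))
  cat(sprintf("  At threshold %.3f: accuracy %.3f, recall %.3f, specificity %.3f\n",
              x$threshold, x$accuracy, x$recall, x$specificity))
  if (!is.null(x$logrank)) {
    cat(sprintf("  Log-rank (high vs low risk): chisq %.2f, p %.2g\n",
                x$logrank$chisq, x$logrank$p))
  }
  invisible(x)
}
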