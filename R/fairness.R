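# Subgroup performance audit: per-subgroup AUROC with bootstrap variance and
# meta-analytic heterogeneity statistics across subgroups.

#' Per-subgroup AUROC estimates with bootstrap variance
#'
#' Computes the AUROC separately within each subgroup, with a percentile
#' bootstrap variance.  Subgroups smaller than `min_size` or containing a
#' single outcome class are excluded and reported in the `excluded`
#' attribute.
#'
#' @param scores Predicted scores or probabilities.
#' @param labels Binary outcome labels (0/1).
#' @param subgroup Subgroup label per observation.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @param min_size Minimum subgroup size to report (default 50).
#' @param var_method `"bootstrap"` (default) or `"hanley"` for the
#'   Hanley-McNeil closed-form AUROC variance (no resampling; the CI is
#'   then a normal approximation).
#' @return data.frame with columns `subgroup`, `theta` (AUROC), `var`
#'   (variance), `lo`, `hi` (95% CI) and `n`; excluded subgroups with
#'   reasons in `attr(, "excluded")`.
#' @export
subgroup_auroc <- function(scores, labels, subgroup, B = 1000, seed = 1,
                           min_size = 50,
                           var_method = c("bootstrap", "hanley")) {
  var_method <- match.arg(var_method)
  stopifnot(length(scores) == length(labels),
            length(labels) == length(subgroup))
  groups <- sort(unique(as.character(subgroup)))
  rows <- list()
  excluded <- character(0)
  set.seed(seed)
  for (g in groups) {
    idx <- which(subgroup == g)
    y <- labels[idx]
    if (length(idx) < min_size) {
      excluded <- c(excluded, sprintf("%s: below minimum size (%d < %d)",
                                      g, length(idx), min_size))
      next
    }
    if (length(unique(y)) < 2) {
      excluded <- c(excluded, sprintf("%s: single outcome class", g))
      next
    }
    s <- scores[idx]
    theta <- auroc(s, y)
    if (var_method == "bootstrap") {
      boot <- replicate(B, {
        b <- sample.int(length(idx), replace = TRUE)
        if (length(unique(y[b])) < 2) NA_real_ else auroc(s[b], y[b])
      })
      boot <- boot[!is.na(boot)]
      v <- stats::var(boot)
      lo <- unname(quantile(boot, 0.025))
      hi <- unname(quantile(boot, 0.975))
    } else {
      n1 <- sum(y == 1)
      n0 <- sum(y == 0)
      q1 <- theta / (2 - theta)
      q2 <- 2 * theta^2 / (1 + theta)
      v <- (theta * (1 - theta) + (n1 - 1) * (q1 - theta^2) +
              (n0 - 1) * (q2 - theta^2)) / (n1 * n0)
      lo <- theta - 1.959964 * sqrt(v)
      hi <- theta + 1.959964 * sqrt(v)
    }
    rows[[g]] <- data.frame(
      subgroup = g, theta = theta, var = v, lo = lo, hi = hi,
      n = length(idx)
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subgroup = character(), theta = numeric(), var = numeric(),
               lo = numeric(), hi = numeric(), n = integer())
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Cochran's Q heterogeneity statistic
#'
#' Inverse-variance-weighted dispersion of subgroup estimates:
#' \deqn{Q = \sum_i w_i (\theta_i - \bar\theta_w)^2, \quad w_i = 1/v_i,}
#' with \eqn{\bar\theta_w} the weighted mean.  The p-value is the upper tail
#' of the chi-squared distribution with `k - 1` degrees of freedom.
#'
#' @param theta Subgroup estimates (e.g. per-subgroup AUROC).
#' @param v Variances of the estimates, strictly positive.
#' @return List with `Q`, `df` and `p`.
#' @export
#' @examples
#' cochran_q(c(0.7, 0.8), c(0.01, 0.01))  # Q = 0.5
cochran_q <- function(theta, v) {
  k <- length(theta)
  if (k < 2) stop("at least two subgroup estimates are required")
  if (any(v <= 0)) stop("variances must be strictly positive")
  w <- 1 / v
  theta_bar <- sum(w * theta) / sum(w)
  Q <- sum(w * (theta - theta_bar)^2)
  list(Q = Q, df = k - 1L, p = stats::pchisq(Q, df = k - 1, lower.tail = FALSE))
}

#' Higgins' I-squared heterogeneity percentage
#'
#' Percentage of total variation across subgroups attributable to true
#' heterogeneity rather than chance:
#' \deqn{I^2 = 100 \cdot \max\left(0, \frac{Q - (k - 1)}{Q}\right),}
#' defined as 0 when `Q = 0`.
#'
#' @param Q Cochran's Q statistic, non-negative.
#' @param k Number of subgroups, at least 2.
#' @return I-squared as a percentage in `[0, 100]`.
#' @export
#' @examples
#' higgins_i2(28.70, 3)
higgins_i2 <- function(Q, k) {
  if (k < 2) stop("k must be at least 2")
  if (Q < 0) stop("Q must be non-negative")
  if (Q == 0) return(0)
  100 * max(0, (Q - (k - 1)) / Q)
}

#' Heterogeneity audit across one subgrouping
#'
#' Convenience wrapper: subgroup AUROCs, Cochran's Q and Higgins' I-squared
#' for a given subgroup labelling.
#'
#' @inheritParams subgroup_auroc
#' @return List with `estimates` (the [subgroup_auroc()] table) and
#'   `heterogeneity` (`Q`, `df`, `p`, `I2`, `k`).
#' @export
audit_subgroups <- function(scores, labels, subgroup, B = 1000, seed = 1,
                            min_size = 50) {
  est <- subgroup_auroc(scores, labels, subgroup, B = B, seed = seed,
                        min_size = min_size)
  # degenerate variance estimates (tiny subgroups whose resampled AUROC is
  # constant) cannot enter the inverse-variance pooling
  usable <- est[est$var > 0, , drop = FALSE]
  if (nrow(usable) < 2) {
    return(list(estimates = est, heterogeneity = NULL))
  }
  q <- cochran_q(usable$theta, usable$var)
  list(estimates = est,
       heterogeneity = list(Q = q$Q, df = q$df, p = q$p,
                            I2 = higgins_i2(q$Q, nrow(usable)),
                            k = nrow(usable)))
}

#' Aggregate the nine ethnicity categories into broad groups
#'
#' Two conventional rollups are supported: `"south_asian"` maps Indian,
#' Pakistani and Bangladeshi to "South Asian" and Caribbean/African to
#' "Black", leaving Chinese, Other Asian and Other ethnic group out of the
#' rollup (`NA`); `"asian"` additionally folds Chinese and Other Asian into
#' a broad "Asian" group.
#'
#' @param ethnicity Character vector of 9-level ethnicity labels.
#' @param scheme `"south_asian"` (default) or `"asian"`.
#' @return Character vector of broad group labels (`NA` where unmapped).
#' @export
ethnicity_rollup <- function(ethnicity, scheme = c("south_asian", "asian")) {
  scheme <- match.arg(scheme)
  out <- rep(NA_character_, length(ethnicity))
  out[ethnicity == "White"] <- "White"
  south_asian <- c("Indian", "Pakistani", "Bangladeshi")
  black <- c("Black Caribbean", "Black African")
  out[ethnicity %in% black] <- "Black"
  if (scheme == "south_asian") {
    out[ethnicity %in% south_asian] <- "South Asian"
  } else {
    out[ethnicity %in% c(south_asian, "Chinese", "Other Asian")] <- "Asian"
  }
  out
}

#' Deprivation quantile groups from Townsend scores
#'
#' Quintile or decile groups computed from the cohort's own empirical
#' distribution (type-7 quantiles); higher group numbers are more deprived.
#'
#' @param townsend Numeric Townsend deprivation scores.
#' @param n_groups 5 (quintiles) or 10 (deciles).
#' @return Integer group labels `1..n_groups`.
#' @export
deprivation_quantile <- function(townsend, n_groups = 5) {
  qs <- quantile(townsend, probs = seq(0, 1, length.out = n_groups + 1),
                 na.rm = TRUE)
  qs[1] <- -Inf
  qs[length(qs)] <- Inf
  as.integer(cut(townsend, breaks = qs, labels = FALSE,
                 include.lowest = TRUE))
}
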