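c_index_oracle <- function(h, t, e) {
  num <- den <- 0
  n <- length(h)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # comparable iff the smaller time is an observed event (strict order)
    if (t[i] == t[j]) next
    first <- if (t[i] < t[j]) i else j
    second <- if (t[i] < t[j]) j else i
    if (e[first] != 1) next
    den <- den + 1
    if (h[first] > h[second]) num <- num + 1
    else if (h[first] == h[second]) num <- num + 0.5
  }
  num / den
}

test_that("auroc reproduces pair-enumeration values and edge cases", {
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auroc(c(1, 2, 3, 10, 20), c(0, 0, 0, 1, 1)), 1)
  expect_equal(auroc(c(1, 1, 1, 1), c(0, 1, 0, 1)), 0.5)
  expect_error(auroc(1:3, c(1, 1, 1)), "both")
  set.seed(1)
  s <- rnorm(5000)
  y <- rbinom(5000, 1, 0.5)
  expect_equal(auroc(s, y), 0.5, tolerance = 0.03)
})

test_that("auroc agrees with pROC on random data including ties", {
  skip_if_not_installed("pROC")
  set.seed(2)
  for (i in 1:20) {
    s <- round(runif(80), 2)
    y <- rbinom(80, 1, 0.4)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(auroc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("bootstrap CI covers the estimate and narrows with sample size", {
  set.seed(3)
  widths <- sapply(c(200, 800, 3200), function(n) {
    s <- rnorm(n)
    y <- rbinom(n, 1, plogis(s))
    ci <- auroc_ci(s, y, B = 300, seed = 4)
    point <- auroc(s, y)
    expect_true(ci["lo"] <= point && point <= ci["hi"])
    unname(ci["hi"] - ci["lo"])
  })
  expect_true(all(diff(widths) < 0))
  # ~1/sqrt(n): a 16x larger sample shrinks the width about 4-fold
  expect_equal(widths[1] / widths[3], 4, tolerance = 0.5)
})

test_that("c_index matches hand-computed values and the pair-counting oracle", {
  expect_equal(c_index(c(3, 2, 1), c(1, 2, 3), c(1, 1, 0)), 1)
  expect_equal(c_index(c(1, 1, 1), c(1, 2, 3), c(1, 1, 1)), 0.5)
  # agrees with survival::concordance whenever times are untied
  set.seed(41)
  for (i in 1:20) {
    n <- 30
    h <- rnorm(n)
    t <- sample(1:1000, n)
    e <- rbinom(n, 1, 0.5)
    if (sum(e) == 0) next
    fit <- survival::concordance(survival::Surv(t, e) ~ h, reverse = TRUE)
    expect_equal(c_index(h, t, e), unname(fit$concordance),
                 tolerance = 1e-12)
  }
  set.seed(5)
  for (i in 1:500) {
    n <- sample(4:20, 1)
    h <- round(rnorm(n), 1)           # ties in scores
    t <- sample(1:8, n, TRUE)         # ties in times
    e <- rbinom(n, 1, 0.6)
    if (sum(e) == 0) next
    ref <- c_index_oracle(h, t, e)
    if (is.nan(ref)) next
    expect_equal(c_index(h, t, e), ref, tolerance = 1e-12)
  }
})

test_that("auroc and c_index coincide without censoring when times invert scores", {
  set.seed(6)
  h <- rnorm(40)
  t <- rank(-h)            # strictly decreasing in the score
  e <- rep(1, 40)
  expect_equal(c_index(h, t, e), 1)
  # binary labels from any time cut then give perfect AUROC as well
  y <- as.integer(t <= median(t))
  expect_equal(auroc(h, y), c_index(h, t, e))
})

test_that("brier score matches direct evaluations", {
  expect_equal(brier(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier(rep(0.5, 10), rbinom(10, 1, 0.5)), 0.25)
  expect_equal(brier(c(0.8, 0.2), c(1, 0)), 0.04)
  expect_error(brier(c(1.2), 1), "p >= 0")
})

test_that("isotonic calibration solves the two-point pooling case and stays monotone", {
  cal <- calibrate_isotonic(c(0.2, 0.8), c(1, 0))
  expect_equal(predict(cal, c(0.2, 0.8)), c(0.5, 0.5))
  # perfectly calibrated monotone input is reproduced at the observed points
  p <- rep(seq(0.1, 0.9, by = 0.2), each = 20)
  set.seed(7)
  y <- rbinom(length(p), 1, p)
  cal2 <- calibrate_isotonic(p, y)
  out <- predict(cal2, sort(runif(100)))
  expect_true(all(diff(out) >= -1e-12))
  obs <- tapply(y, p, mean)
  if (all(diff(obs) >= 0)) {
    expect_equal(predict(cal2, as.numeric(names(obs))),
                 as.numeric(obs), tolerance = 1e-9)
  }
})

test_that("decile table partitions the cohort", {
  set.seed(8)
  p <- runif(500)
  y <- rbinom(500, 1, p)
  tab <- decile_table(p, y)
  expect_equal(sum(tab$n), 500)
  expect_equal(nrow(tab), 10)
  expect_true(all(diff(tab$mean_pred) > 0))
})

test_that("thresholded classification reproduces confusion-matrix arithmetic", {
  y <- rep(c(1, 1, 0, 0), c(40, 10, 60, 890))
  p <- rep(c(0.9, 0.1, 0.9, 0.1), c(40, 10, 60, 890))
  m <- classify_at_threshold(p, y, 0.5)
  expect_equal(unname(m["accuracy"]), 0.93)
  expect_equal(unname(m["recall"]), 0.8)
  expect_equal(unname(m["specificity"]), 0.936842, tolerance = 1e-6)
  m0 <- classify_at_threshold(p, y, 0)
  expect_equal(unname(m0["recall"]), 1)
  expect_equal(unname(m0["specificity"]), 0)
  m1 <- classify_at_threshold(p, y, 1)
  expect_equal(unname(m1["specificity"]), 1)
})

test_that("Youden threshold maximizes sensitivity + specificity", {
  y <- c(0, 0, 0, 1, 1, 1)
  p <- c(0.1, 0.2, 0.6, 0.5, 0.7, 0.9)
  th <- youden_threshold(p, y)
  j <- function(t) sum(classify_at_threshold(p, y, t)[c("recall",
                                                        "specificity")]) - 1
  expect_true(all(j(th) >= sapply(unique(p), j)))
})

test_that("KM curves match the hand-computed product-limit table", {
  t <- c(1, 2, 3, 4)
  e <- c(1, 0, 1, 0)
  km <- km_curve(t, e, rep("all", 4), min_at_risk = 0)
  expect_equal(km$surv[km$time == 1], 0.75)
  expect_equal(km$surv[km$time == 3], 0.375)
  none <- km_curve(1:5, rep(0, 5), rep("all", 5), min_at_risk = 0)
  expect_true(all(none$surv == 1))
  expect_error(km_curve(numeric(0), numeric(0), character(0)), "empty")
  # suppression flag beyond the at-risk floor
  km2 <- km_curve(1:30, rep(1, 30), rep("all", 30))
  expect_true(all(km2$suppressed == (km2$n_risk < 10)))
})

test_that("log-rank test is null for identical groups and matches survdiff", {
  t <- rep(c(5, 10, 15, 20), 2)
  e <- rep(c(1, 0, 1, 1), 2)
  g <- rep(c("a", "b"), each = 4)
  lr <- logrank(t, e, g)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
  expect_error(logrank(t, e, rep("a", 8)), "two groups")
})

test_that("risk stratification uses inclusive sex-specific thresholds", {
  expect_equal(stratify_risk(c(0.41, 0.40, 0.39), rep("male", 3)),
               c("high", "high", "low"))
  expect_equal(stratify_risk(c(0.34, 0.33), rep("female", 2)),
               c("high", "low"))
  expect_error(stratify_risk(0.5, "other"), "sex")
})
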