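test_that("windowed resolution prefers the nearest in-window record", {
  rec <- data.frame(day = c(-400, -100), value = c("heavy smoker",
                                                   "ex-smoker"))
  expect_equal(resolve_windowed(rec, "smoking", 0, kind = "status"),
               "ex-smoker")
  # no in-window record: most recent prior status wins
  rec2 <- data.frame(day = -700, value = "light smoker")
  expect_equal(resolve_windowed(rec2, "smoking", 0, kind = "status"),
               "light smoker")
  # medication: any prior prescription sets the flag; none ever -> 0
  rx <- data.frame(day = -900, value = 1)
  expect_equal(resolve_windowed(rx, "corticosteroid", 0, kind = "medication"),
               1L)
  none <- data.frame(day = numeric(0), value = numeric(0))
  expect_equal(resolve_windowed(none, "corticosteroid", 0,
                                kind = "medication"), 0L)
  # comorbidity onset strictly before entry
  on <- data.frame(day = c(-10), value = 1)
  expect_equal(resolve_windowed(on, "af", 0, kind = "onset"), 1L)
  expect_equal(resolve_windowed(data.frame(day = 5, value = 1), "af", 0,
                                kind = "onset"), 0L)
})

test_that("linear imputation reproduces hand-computed extrapolations", {
  pts <- data.frame(day = c(-600, -400, -200), value = c(120, 125, 130))
  expect_equal(impute_linear(pts, 0), 135)
  expect_true(is.na(impute_linear(pts[1:2, ], 0)))
  const <- data.frame(day = c(-600, -400, -200), value = c(120, 120, 120))
  expect_equal(impute_linear(const, 0), 120)
  # only points within the 730-day look-back qualify
  far <- data.frame(day = c(-900, -400, -200), value = c(0, 125, 130))
  expect_true(is.na(impute_linear(far, 0)))
  # duplicate days with conflicting values are averaged before the fit
  dup <- data.frame(day = c(-600, -600, -400, -200),
                    value = c(118, 122, 125, 130))
  expect_equal(impute_linear(dup, 0), 135)
})

test_that("linear imputation agrees with an lm oracle on 1000 random point sets", {
  set.seed(17)
  for (i in 1:1000) {
    k <- sample(3:6, 1)
    days <- sort(sample(seq(-730, -1), k))
    vals <- rnorm(k, 100, 10)
    got <- impute_linear(data.frame(day = days, value = vals), 0)
    fit <- lm(vals ~ days)
    ref <- unname(predict(fit, data.frame(days = 0)))
    expect_equal(got, ref, tolerance = 1e-9)
  }
})

test_that("vectorized resolution matches the scalar rules on a real cohort", {
  co <- small_cohort()
  eps <- small_episodes()
  meas <- as.data.frame(co$measurements)
  set.seed(8)
  rows <- sample(nrow(eps), 40)
  for (r in rows) {
    v <- "sbp"
    pts <- meas[meas$patient_id == eps$patient_id[r] & meas$variable == v,
                c("day", "value")]
    entry_day <- (eps$entry_age[r] - 40) * 365
    d <- abs(pts$day - entry_day)
    ref <- if (nrow(pts) && min(d) <= 183) {
      pts$value[which.min(d)]
    } else {
      impute_linear(pts, entry_day)
    }
    expect_equal(eps[[v]][r], ref, tolerance = 1e-9)
  }
})

test_that("QC removes out-of-bound values and logs them", {
  eps <- data.frame(sbp = c(120, 300, 130), bmi = c(25, 22, 12),
                    dbp = c(80, 80, 80), tchol_hdl_ratio = c(4, 4, 4))
  res <- qc_filter(eps)
  expect_equal(nrow(res$kept), 1)
  expect_setequal(res$log$variable, c("sbp", "bmi"))
  expect_setequal(res$log$value, c(300, 12))
  clean <- qc_filter(eps[1, ])
  expect_equal(nrow(clean$kept), 1)
  expect_equal(nrow(clean$log), 0)
})

test_that("min-max scaler follows the fit/transform contract", {
  train <- data.frame(sbp = c(100, 150, 200), bmi = c(20, 20, 20))
  st <- fit_scaler(train, vars = c("sbp", "bmi"))
  out <- transform_scale(st, data.frame(sbp = 150, bmi = 20))
  expect_equal(out$sbp, 0.5)
  expect_equal(out$bmi, 0)   # constant feature maps to 0
  # non-training values clip to [0, 1]
  expect_equal(transform_scale(st, data.frame(sbp = 250, bmi = 20))$sbp, 1)
  expect_equal(transform_scale(st, data.frame(sbp = 50, bmi = 20))$sbp, 0)
  expect_error(transform_scale(list(), train), "state error")
})

test_that("scaling then inverse scaling is the identity on training data", {
  set.seed(3)
  train <- data.frame(sbp = runif(50, 90, 200), bmi = runif(50, 17, 45))
  st <- fit_scaler(train, vars = c("sbp", "bmi"))
  back <- inverse_scale(st, transform_scale(st, train))
  expect_equal(back$sbp, train$sbp, tolerance = 1e-9)
  expect_equal(back$bmi, train$bmi, tolerance = 1e-9)
})

test_that("stratified splitting hits exact sizes and per-stratum rates", {
  set.seed(1)
  eps <- data.frame(event = rep(c(0, 1), c(900, 100)),
                    sex = rep(c("male", "female"), 500))
  sp <- split_dataset(eps, seed = 5)
  expect_equal(as.vector(table(sp)[c("train", "val", "test")]),
               c(700L, 150L, 150L))
  # per-stratum counts within 1 episode of the ratio-implied counts
  for (s in unique(paste(eps$event, eps$sex))) {
    idx <- paste(eps$event, eps$sex) == s
    counts <- table(factor(sp[idx], levels = c("train", "val", "test")))
    expect_true(all(abs(counts - sum(idx) * c(0.7, 0.15, 0.15)) <= 1))
  }
  expect_identical(sp, split_dataset(eps, seed = 5))
  expect_false(identical(sp, split_dataset(eps, seed = 6)))
  expect_error(split_dataset(eps, ratios = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("split assignment is a partition across a 100-seed sweep", {
  eps <- data.frame(event = rbinom(240, 1, 0.2),
                    sex = sample(c("male", "female"), 240, TRUE))
  for (s in 1:100) {
    sp <- split_dataset(eps, seed = s)
    expect_true(all(sp %in% c("train", "val", "test")))
    expect_length(sp, 240)
  }
})

test_that("patient-grouped splits keep every patient in one partition", {
  eps <- small_episodes()
  sp <- split_dataset(eps, seed = 3, group = eps$patient_id)
  per_patient <- tapply(sp, eps$patient_id, function(x) length(unique(x)))
  expect_true(all(per_patient == 1))
})

test_that("k-fold assignment balances fold sizes and event rates", {
  eps <- data.frame(event = rep(c(0, 1), c(900, 100)),
                    sex = rep("male", 1000))
  f <- split_kfold(eps, k = 10, seed = 2)
  expect_equal(as.vector(table(f)), rep(100L, 10))
  ev <- tapply(eps$event, f, sum)
  expect_true(all(abs(ev - 10) <= 1))
  expect_identical(f, split_kfold(eps, k = 10, seed = 2))
  expect_error(split_kfold(eps, k = 1), "k must be")
})

test_that("class weights follow the balanced scheme with rate scaling", {
  w <- class_weights(rep(c(0, 1), each = 50))
  expect_equal(unname(w["w_pos"] / w["w_neg"]), 1)
  w2 <- class_weights(rep(c(0, 1), c(90, 10)))
  expect_equal(unname(w2["w_pos"] / w2["w_neg"]), 9)
  # beta = 0 makes the weights independent of the reference rate
  expect_equal(class_weights(rep(c(0, 1), c(90, 10)), r_ref = 0.5),
               class_weights(rep(c(0, 1), c(90, 10)), r_ref = 0.01))
  # frequency-weighted mean weight is 1
  lab <- rep(c(0, 1), c(80, 20))
  w3 <- class_weights(lab, beta = 0.5)
  expect_equal(mean(ifelse(lab == 1, w3["w_pos"], w3["w_neg"])), 1,
               tolerance = 1e-12)
  expect_error(class_weights(rep(1, 10)), "both classes")
})
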