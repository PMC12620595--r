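test_that("cohort generation is byte-identical for a fixed seed", {
  spec <- cohort_spec(n_patients = 120, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$patients, b$patients)
  expect_identical(a$measurements, b$measurements)
})

test_that("degenerate and invalid ethnicity mixtures behave as specified", {
  probs <- setNames(rep(0, 9), riskfusion:::ETHNICITY_LEVELS)
  probs["White"] <- 1
  co <- generate_cohort(cohort_spec(n_patients = 80, seed = 1,
                                    ethnicity_probs = probs))
  expect_true(all(co$patients$ethnicity == "White"))
  bad <- probs
  bad["White"] <- 0.8
  expect_error(cohort_spec(ethnicity_probs = bad), "sum to 1")
  expect_error(cohort_spec(horizon_days = 0), "horizon")
  expect_error(cohort_spec(weibull_shape = -1), "shape")
})

test_that("spatial preset reproduces the minority-enriched White proportion", {
  n <- 20000
  co <- generate_cohort(cohort_spec("spatial", n_patients = n, seed = 5))
  p_white <- mean(co$patients$ethnicity == "White")
  target <- unname(co$spec$ethnicity_probs["White"])
  expect_equal(target, 0.652, tolerance = 0.001)
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(p_white - target), 3 * se)
})

test_that("null-coefficient event rate matches the closed-form Weibull CDF", {
  spec <- cohort_spec(n_patients = 10000, seed = 21, beta = c(sbp = 0))
  co <- generate_cohort(spec)
  # with lp = 0 for everyone, P(event age within the horizon of age 40)
  # equals the calibrated baseline rate exactly
  for (s in c("male", "female")) {
    pat <- co$patients[co$patients$sex == s, ]
    rate_hat <- mean((pat$cvd_event_age - 40) * 365 <= spec$horizon_days)
    rate <- unname(spec$baseline_event_rate[s])
    se <- sqrt(rate * (1 - rate) / nrow(pat))
    expect_lt(abs(rate_hat - rate), 3 * se)
  }
})

test_that("doubling a positive coefficient strictly increases the event rate", {
  rate_for <- function(mult) {
    spec <- cohort_spec(n_patients = 10000, seed = 33,
                        beta = c(sbp = 0.45 * mult))
    co <- generate_cohort(spec)
    mean((co$patients$cvd_event_age - 40) * 365 <= spec$horizon_days)
  }
  expect_gt(rate_for(2), rate_for(1))
})

test_that("simulate_outcomes respects truncation, grace labelling and preconditions", {
  spec <- cohort_spec(n_patients = 10, seed = 2)
  hist <- toy_history()
  set.seed(99)
  draws <- replicate(200, simulate_outcomes(hist, spec, 40), simplify = FALSE)
  tte <- vapply(draws, `[[`, numeric(1), "tte_days")
  ev <- vapply(draws, `[[`, numeric(1), "event")
  expect_true(all(tte >= 1 & tte <= 3650))
  expect_true(all(tte[ev == 0] == 3650))
  expect_error(simulate_outcomes(toy_history(event_age = 50), spec, 55),
               "precede")
})

test_that("episode extraction matches the hand-traced example", {
  spec <- cohort_spec(n_patients = 10, seed = 2)
  eps <- extract_episodes(toy_history(event_age = 52), spec)
  expect_equal(eps$entry_age, c(40L, 45L, 50L))
  expect_equal(eps$event, c(0L, 1L, 1L))
  expect_equal(eps$tte_days, c(3650L, 2555L, 730L))
  # an event before the first candidate entry yields no episodes
  expect_equal(nrow(extract_episodes(toy_history(event_age = 39), spec)), 0)
  # boundary: event exactly horizon + grace days after entry stays positive
  # with the time capped at the horizon
  h <- toy_history(event_age = 40 + 3833 / 365)
  b <- extract_episodes(h, spec)
  expect_equal(b$event[1], 1L)
  expect_equal(b$tte_days[1], 3650L)
  # one day beyond the grace window is censored
  h2 <- toy_history(event_age = 40 + 3834 / 365)
  expect_equal(extract_episodes(h2, spec)$event[1], 0L)
})

test_that("registration age limits candidate entries", {
  spec <- cohort_spec(n_patients = 10, seed = 2)
  eps <- extract_episodes(toy_history(registration_age = 57), spec)
  expect_equal(min(eps$entry_age), 60L)
})

test_that("vectorized episode table agrees with per-patient extraction", {
  co <- small_cohort()
  eps <- small_episodes()
  set.seed(4)
  sample_ids <- sample(co$patients$patient_id, 60)
  for (pid in sample_ids) {
    hist <- co$patients[co$patients$patient_id == pid, ]
    ref <- extract_episodes(hist, co$spec)
    got <- eps[eps$patient_id == pid,
               c("patient_id", "entry_age", "event", "tte_days")]
    rownames(got) <- NULL
    expect_equal(got, ref)
  }
})

test_that("censored episodes sit exactly at the horizon", {
  eps <- small_episodes()
  expect_true(all(eps$tte_days[eps$event == 0] == 3650L))
  expect_true(all(eps$tte_days >= 1 & eps$tte_days <= 3650))
  expect_true(all(eps$entry_age %in% seq(40L, 75L, 5L)))
})

test_that("cohort CSV round-trips with its generator sidecar", {
  co <- generate_cohort(cohort_spec(n_patients = 40, seed = 13))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  eps <- read_cohort(dir)
  expect_equal(nrow(eps), nrow(build_episode_table(co)))
  gen <- attr(eps, "generator")
  expect_equal(gen$seed, 13)
  expect_equal(gen$beta$sbp, 0.45)
})
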