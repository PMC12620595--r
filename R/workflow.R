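# End-to-end orchestration: simulate -> prepare -> train -> evaluate ->
# audit, driven by a single YAML config, with a reproducibility manifest.

#' Evaluate a trained model on a partition
#'
#' Runs the evaluation-mode forward pass on the test partition, assembles
#' the [metric_report()] (calibrator and threshold fitted on validation)
#' and returns the per-episode predictions.
#'
#' @param trained A `trained_model` from [train_model()].
#' @param prepared The `prepared_data` the model was trained on.
#' @param split_eval Partition to evaluate (default `"test"`).
#' @param B Bootstrap resamples for confidence intervals.
#' @param seed Seed for the bootstrap.
#' @return List with `report` (a `metric_report`), `predictions`
#'   (data.frame incl. identifiers and outcomes) and `val_predictions`.
#' @export
evaluate_model <- function(trained, prepared, split_eval = "test", B = 1000,
                           seed = 1) {
  stopifnot(inherits(trained, "trained_model"))
  branches <- trained$train_config$branches
  part <- function(lab) {
    idx <- which(prepared$split == lab)
    pred <- hybrid_predict(trained$model, trained$ids[idx, , drop = FALSE],
                           prepared$features[idx, , drop = FALSE],
                           branches = branches)
    eps <- prepared$episodes[idx, ]
    cbind(eps[, c("patient_id", "entry_age", "sex", "ethnicity",
                  "townsend", "deprivation_quantile", "event", "tte_days")],
          pred)
  }
  test_df <- part(split_eval)
  val_df <- part("val")
  rep <- metric_report(
    test = list(prob = test_df$prob, hazard = test_df$hazard,
                t = test_df$tte_days, e = test_df$event, sex = test_df$sex),
    val = list(prob = val_df$prob, hazard = val_df$hazard,
               t = val_df$tte_days, e = val_df$event, sex = val_df$sex),
    B = B, seed = seed)
  list(report = rep, predictions = test_df, val_predictions = val_df)
}

#' Subgroup fairness audit of a prediction table
#'
#' Heterogeneity of subgroup AUROC across ethnicity (9-level and broad
#' rollup) and Townsend deprivation quantiles.
#'
#' @param predictions data.frame with `prob`, `event`, `ethnicity`,
#'   `townsend` columns (as produced by [evaluate_model()]).
#' @param B Bootstrap resamples per subgroup.
#' @param seed Seed.
#' @param min_size Minimum subgroup size.
#' @return Named list of [audit_subgroups()] results: `ethnicity_9`,
#'   `ethnicity_3`, `deprivation_5`, `deprivation_10`.
#' @export
fairness_audit <- function(predictions, B = 1000, seed = 1, min_size = 50) {
  p <- predictions$prob
  y <- predictions$event
  list(
    ethnicity_9 = audit_subgroups(p, y, predictions$ethnicity, B = B,
                                  seed = seed, min_size = min_size),
    ethnicity_3 = audit_subgroups(
      p, y, ethnicity_rollup(predictions$ethnicity), B = B, seed = seed,
      min_size = min_size),
    deprivation_5 = audit_subgroups(
      p, y, deprivation_quantile(predictions$townsend, 5), B = B,
      seed = seed, min_size = min_size),
    deprivation_10 = audit_subgroups(
      p, y, deprivation_quantile(predictions$townsend, 10), B = B,
      seed = seed, min_size = min_size)
  )
}

required_config_keys <- c("simulate", "train", "loss")

read_run_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  missing <- setdiff(required_config_keys, names(cfg))
  if (length(missing)) {
    stop("config error: missing section(s): ", paste(missing, collapse = ", "))
  }
  cfg
}

#' Run a full experiment from a config
#'
#' Executes simulate, prepare, train, evaluate and audit in order, writing
#' all artifacts plus a reproducibility manifest (config hash, seeds, file
#' digests, timestamps) to the output directory.  The manifest is written
#' even when a stage fails; the error then names the failing stage.
#'
#' @param config Path to a YAML config, or an equivalent named list.
#'   Required sections: `simulate` (`preset`, `n`, `seed`, optional
#'   `signal`), `train` (epochs etc.), `loss` (`gamma`, `alpha`, `mode`).
#'   Optional: `prepare`, `model`, `evaluate`, `audit`, `out`.
#' @param out Output directory (overrides the config's `out`).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the trained model, report, audit results
#'   and the manifest.
#' @export
run_experiment <- function(config, out = NULL, verbose = FALSE) {
  cfg <- read_run_config(config)
  if (is.null(out)) out <- cfg$out
  if (is.null(out)) stop("config error: missing output directory ('out')")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    config = cfg,
    package_version = as.character(utils::packageVersion("riskfusion")),
    started = format(Sys.time(), tz = "UTC"),
    stages = list(), digests = list()
  )
  stage <- "simulate"
  result <- list()
  on.exit({
    manifest$finished <- format(Sys.time(), tz = "UTC")
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  })
  run_stage <- function(name, fun) {
    stage <<- name
    if (verbose) message("stage: ", name)
    t0 <- Sys.time()
    val <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok", seconds = round(as.numeric(Sys.time() - t0, "secs"), 2))
    val
  }
  digest_files <- function(paths) {
    for (p in paths) {
      manifest$digests[[basename(p)]] <<- unname(tools::md5sum(p))
    }
  }
  sim <- cfg$simulate
  cohort <- run_stage("simulate", function() {
    spec <- cohort_spec(preset = sim$preset %||% "development",
                        n_patients = sim$n %||% 2000,
                        seed = sim$seed %||% 1,
                        signal = sim$signal %||% 1)
    co <- generate_cohort(spec)
    digest_files(write_cohort(co, file.path(out, "cohort")))
    co
  })
  prepared <- run_stage("prepare", function() {
    pr <- cfg$prepare
    prep <- prepare_dataset(cohort,
                            ratios = unlist(pr$ratios) %||% c(0.7, 0.15, 0.15),
                            seed = pr$seed %||% (sim$seed %||% 1))
    writeLines(prep$narratives, file.path(out, "narratives.txt"))
    utils::write.csv(data.frame(split = prep$split),
                     file.path(out, "split.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(class_weights = as.list(prep$class_weights),
           scaler = prep$scaler$ranges),
      file.path(out, "preprocess.json"), auto_unbox = TRUE, digits = NA)
    digest_files(file.path(out, c("narratives.txt", "split.csv",
                                  "preprocess.json")))
    prep
  })
  trained <- run_stage("train", function() {
    mc <- do.call(model_config, c(cfg$model %||% list()))
    tcfg <- cfg$train
    tcfg$gamma <- cfg$loss$gamma %||% 2
    tcfg$alpha <- cfg$loss$alpha %||% 0.25
    tcfg$loss_mode <- cfg$loss$mode %||% "focal_cox"
    if (!is.null(tcfg$branches)) tcfg$branches <- unlist(tcfg$branches)
    tr <- do.call(train_config, tcfg[setdiff(names(tcfg), "n")])
    fit <- train_model(prepared, mc, tr, verbose = verbose)
    utils::write.csv(fit$history, file.path(out, "history.csv"),
                     row.names = FALSE)
    save_checkpoint(fit$model, file.path(out, "checkpoint.rds"),
                    epoch = fit$best_epoch)
    jsonlite::write_json(
      list(best_epoch = fit$best_epoch,
           val_auroc = fit$history$val_auroc[fit$best_epoch],
           val_c_index = fit$history$val_c_index[fit$best_epoch]),
      file.path(out, "selection.json"), auto_unbox = TRUE, digits = NA)
    digest_files(file.path(out, c("history.csv", "selection.json")))
    fit
  })
  evald <- run_stage("evaluate", function() {
    ev <- cfg$evaluate
    res <- evaluate_model(trained, prepared, B = ev$B %||% 1000,
                          seed = ev$seed %||% 1)
    utils::write.csv(res$predictions, file.path(out, "predictions.csv"),
                     row.names = FALSE)
    utils::write.csv(res$report$calibration, file.path(out, "deciles.csv"),
                     row.names = FALSE)
    utils::write.csv(res$report$km, file.path(out, "km.csv"),
                     row.names = FALSE)
    write_metric_report(res$report, file.path(out, "report.json"))
    plot_km_png(res$report$km, file.path(out, "km.png"))
    plot_calibration_png(res$report$calibration,
                         file.path(out, "calibration.png"))
    digest_files(file.path(out, c("predictions.csv", "deciles.csv",
                                  "km.csv", "report.json")))
    res
  })
  audit <- run_stage("audit", function() {
    au <- cfg$audit
    res <- fairness_audit(evald$predictions, B = au$B %||% 1000,
                          seed = au$seed %||% 1,
                          min_size = au$min_size %||% 50)
    het <- lapply(res, function(x) x$heterogeneity)
    jsonlite::write_json(het, file.path(out, "heterogeneity.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    est <- do.call(rbind, lapply(names(res), function(nm) {
      e <- res[[nm]]$estimates
      if (is.null(e) || nrow(e) == 0) return(NULL)
      cbind(grouping = nm, e)
    }))
    if (is.null(est)) {
      est <- data.frame(grouping = character(), subgroup = character(),
                        theta = numeric(), var = numeric(), n = integer())
    }
    utils::write.csv(est, file.path(out, "subgroups.csv"), row.names = FALSE)
    digest_files(file.path(out, c("heterogeneity.json", "subgroups.csv")))
    res
  })
  manifest$test_digest <- manifest$digests[["predictions.csv"]]
  invisible(list(cohort = cohort, prepared = prepared, trained = trained,
                 evaluation = evald, audit = audit, manifest = manifest,
                 out = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a metric report as JSON
#'
#' @param report A `metric_report`.
#' @param path Destination file.
#' @export
write_metric_report <- function(report, path) {
  out <- unclass(report)
  out$risk_groups <- as.list(out$risk_groups)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  invisible(path)
}

plot_km_png <- function(km, path) {
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  groups <- unique(km$group)
  cols <- c(high = "firebrick", low = "steelblue")
  graphics::plot(NULL, xlim = c(0, max(km$time)), ylim = c(0, 1),
                 xlab = "Days since entry", ylab = "Event-free probability",
                 main = "Risk-stratified survival")
  for (g in groups) {
    d <- km[km$group == g & !km$suppressed, ]
    if (!nrow(d)) next
    graphics::lines(stats::stepfun(d$time, c(1, d$surv)), do.points = FALSE,
                    col = cols[[g]] %||% "grey40", lwd = 2)
    graphics::lines(stats::stepfun(d$time, c(1, d$lower)), do.points = FALSE,
                    col = cols[[g]] %||% "grey40", lty = 3)
    graphics::lines(stats::stepfun(d$time, c(1, d$upper)), do.points = FALSE,
                    col = cols[[g]] %||% "grey40", lty = 3)
  }
  graphics::legend("bottomleft", legend = groups,
                   col = unname(cols[groups]), lwd = 2)
}

plot_calibration_png <- function(deciles, path) {
  grDevices::png(path, width = 700, height = 700)
  on.exit(grDevices::dev.off())
  lim <- range(c(deciles$mean_pred, deciles$obs_rate, 0))
  graphics::plot(deciles$mean_pred, deciles$obs_rate, xlim = lim, ylim = lim,
                 pch = 19, xlab = "Mean predicted risk",
                 ylab = "Observed event rate",
                 main = "Calibration by predicted-risk decile")
  graphics::abline(0, 1, lty = 2)
  graphics::lines(deciles$mean_pred, deciles$obs_rate, col = "steelblue")
}

#' Compare two evaluated runs
#'
#' Paired comparison of two runs on the identical test partition: metric
#' deltas with percentile bootstrap confidence intervals on the paired
#' difference.  Refuses to compare runs whose test-set digests differ.
#'
#' @param dir_a,dir_b Output directories of two [run_experiment()] runs.
#' @param B Bootstrap resamples.
#' @param seed Seed.
#' @return data.frame with one row per metric: delta (A - B) and CI.
#' @export
compare_runs <- function(dir_a, dir_b, B = 1000, seed = 1) {
  man_a <- jsonlite::read_json(file.path(dir_a, "manifest.json"))
  man_b <- jsonlite::read_json(file.path(dir_b, "manifest.json"))
  key_a <- man_a$digests[["episodes.csv"]]
  key_b <- man_b$digests[["episodes.csv"]]
  if (is.null(key_a) || is.null(key_b) || !identical(key_a, key_b)) {
    stop("test digest mismatch: runs were not evaluated on the same data")
  }
  pa <- utils::read.csv(file.path(dir_a, "predictions.csv"))
  pb <- utils::read.csv(file.path(dir_b, "predictions.csv"))
  if (!identical(pa$patient_id, pb$patient_id) ||
      !identical(pa$entry_age, pb$entry_age)) {
    stop("test digest mismatch: prediction rows differ between runs")
  }
  set.seed(seed)
  n <- nrow(pa)
  metrics <- function(d) {
    c(auroc = auroc(d$prob, d$event),
      c_index = c_index(d$hazard, d$tte_days, d$event),
      brier = brier(pmin(pmax(d$prob, 0), 1), d$event))
  }
  point <- metrics(pa) - metrics(pb)
  boot <- replicate(B, {
    idx <- sample.int(n, replace = TRUE)
    if (length(unique(pa$event[idx])) < 2) return(rep(NA_real_, 3))
    metrics(pa[idx, ]) - metrics(pb[idx, ])
  })
  lo <- apply(boot, 1, quantile, 0.025, na.rm = TRUE)
  hi <- apply(boot, 1, quantile, 0.975, na.rm = TRUE)
  data.frame(metric = names(point), delta = unname(point),
             lo = unname(lo), hi = unname(hi))
}
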