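# Two-stage multitask training: uncertainty parameters frozen for the first
# stage, then learnable; AdamW with cosine annealing and warm restarts,
# gradient clipping, early stopping, and composite AUROC/C-index model
# selection.

#' Training configuration
#'
#' @param epochs Maximum epochs (default 30).
#' @param batch_size Mini-batch size (default 64); the trailing partial
#'   batch is merged into its predecessor whenever it would fall below
#'   `min_event_batch`, so Cox risk sets keep adequate context.
#' @param min_event_batch Smallest admissible batch when events are present
#'   (default 64).
#' @param lr Initial learning rate (default 3e-4).
#' @param weight_decay Decoupled weight decay (default 1e-4).
#' @param clip Global gradient-norm clip (default 1).
#' @param patience Early-stopping patience on the validation composite
#'   score (default 5).
#' @param min_epochs Epochs to complete before early stopping may trigger
#'   (default 12): the warm-restart schedule makes validation scores
#'   non-monotone within a cycle, so stopping inside the first annealing
#'   trough would discard the restart the schedule is built around.
#' @param sigma_freeze_epochs Epochs during which the task-uncertainty
#'   parameters stay at initialization (default 10).
#' @param t0,t_mult Warm-restart schedule (defaults 10 and 2).
#' @param gamma,alpha Focal loss parameters (defaults 2 and 0.25).
#' @param loss_mode `"focal_cox"` (default), `"focal_only"` or
#'   `"cox_only"`.
#' @param branches Branch ablation: subset of `c("text", "structured")`.
#' @param seed Training seed (shuffling, dropout).
#' @return Object of class `train_config`.
#' @export
train_config <- function(epochs = 30, batch_size = 64, min_event_batch = 64,
                         lr = 3e-4, weight_decay = 1e-4, clip = 1,
                         patience = 5, min_epochs = 12,
                         sigma_freeze_epochs = 10, t0 = 10,
                         t_mult = 2, gamma = 2, alpha = 0.25,
                         loss_mode = c("focal_cox", "focal_only", "cox_only"),
                         branches = c("text", "structured"), seed = 1) {
  loss_mode <- match.arg(loss_mode)
  stopifnot(all(branches %in% c("text", "structured")), length(branches) >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 min_event_batch = as.integer(min_event_batch), lr = lr,
                 weight_decay = weight_decay, clip = clip,
                 patience = as.integer(patience),
                 min_epochs = as.integer(min_epochs),
                 sigma_freeze_epochs = as.integer(sigma_freeze_epochs),
                 t0 = t0, t_mult = t_mult, gamma = gamma, alpha = alpha,
                 loss_mode = loss_mode, branches = branches,
                 seed = as.integer(seed)),
            class = "train_config")
}

batch_indices <- function(idx, batch_size, min_batch) {
  n <- length(idx)
  starts <- seq(1, n, by = batch_size)
  batches <- lapply(starts, function(s) idx[s:min(s + batch_size - 1, n)])
  k <- length(batches)
  if (k > 1 && length(batches[[k]]) < min_batch) {
    batches[[k - 1]] <- c(batches[[k - 1]], batches[[k]])
    batches[[k]] <- NULL
  }
  batches
}

#' Train the hybrid multitask model
#'
#' @param prepared A `prepared_data` bundle from [prepare_dataset()].
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @param tokenizer Optional `wordpiece_tokenizer`; defaults to the packaged
#'   vocabulary.
#' @param verbose Print per-epoch progress.
#' @return Object of class `trained_model`: the selected `model`, the full
#'   per-epoch `history` (losses, validation AUROC/C-index, sigma values),
#'   `best_epoch`, tokenized inputs and split bookkeeping for evaluation.
#' @export
train_model <- function(prepared, config = model_config(),
                        tc = train_config(), tokenizer = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(prepared, "prepared_data"))
  if (is.null(tokenizer)) tokenizer <- load_tokenizer()
  if (!any(prepared$split == "train") || !any(prepared$split == "val")) {
    stop("configuration error: train and val partitions are required")
  }
  toks <- tokenize_all(prepared$narratives, tokenizer,
                       max_tokens = config$max_tokens)
  # trim the common padding tail: every sequence keeps its sentinels
  t_eff <- max(toks$n_tokens)
  ids <- toks$ids[, seq_len(t_eff), drop = FALSE]
  feats <- prepared$features
  y <- prepared$episodes$event
  tte <- prepared$episodes$tte_days
  model <- init_model(config, vocab_size = length(tokenizer$vocab),
                      n_features = ncol(feats))
  sigma_init <- c(model$params$log_sigma_focal, model$params$log_sigma_cox)
  cw <- prepared$class_weights
  w_all <- ifelse(y == 1, cw["w_pos"], cw["w_neg"])
  train_idx <- which(prepared$split == "train")
  val_idx <- which(prepared$split == "val")
  opt <- adamw_init(model$params)
  history <- list()
  best <- list(score = -Inf, epoch = 0L, params = NULL)
  patience_left <- tc$patience
  n_batches <- max(1, ceiling(length(train_idx) / tc$batch_size))
  for (epoch in seq_len(tc$epochs)) {
    set.seed(tc$seed * 10000 + epoch)
    shuffled <- train_idx[sample.int(length(train_idx))]
    batches <- batch_indices(shuffled, tc$batch_size, tc$min_event_batch)
    frozen <- if (epoch <= tc$sigma_freeze_epochs)
      c("log_sigma_focal", "log_sigma_cox") else character(0)
    if (tc$loss_mode != "focal_cox") {
      frozen <- unique(c(frozen, "log_sigma_focal", "log_sigma_cox"))
    }
    ep_lf <- 0
    ep_lc <- 0
    ep_lt <- 0
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      fw <- hybrid_fwd(model, ids[b, , drop = FALSE],
                       feats[b, , drop = FALSE], train = TRUE,
                       branches = tc$branches)
      yb <- y[b]
      wb <- w_all[b]
      lf <- focal_loss(fw$prob, yb, tc$gamma, tc$alpha, wb)
      lc <- cox_loss(fw$hazard, tte[b], yb)
      sf <- exp(model$params$log_sigma_focal)
      sc <- exp(model$params$log_sigma_cox)
      gl <- focal_loss_grad_logit(fw$logit, yb, tc$gamma, tc$alpha, wb)
      gc <- cox_loss_grad(fw$hazard, tte[b], yb)
      if (tc$loss_mode == "focal_cox") {
        lt <- combined_loss(lf, lc, sf, sc)
        dlogit <- gl / (2 * sf^2)
        dhaz <- gc / (2 * sc^2)
      } else if (tc$loss_mode == "focal_only") {
        lt <- lf
        dlogit <- gl
        dhaz <- numeric(length(b))
      } else {
        lt <- lc
        dlogit <- numeric(length(b))
        dhaz <- gc
      }
      grads <- hybrid_bwd(model, fw, dlogit, dhaz)
      if (tc$loss_mode == "focal_cox" && !length(frozen)) {
        grads$log_sigma_focal <-
          combined_loss_grad_logsigma(lf, model$params$log_sigma_focal)
        grads$log_sigma_cox <-
          combined_loss_grad_logsigma(lc, model$params$log_sigma_cox)
      }
      grads <- clip_gradients(grads, tc$clip)
      lr_now <- cosine_warm_restart_lr(epoch - 1 + (bi - 1) / n_batches,
                                       tc$lr, t0 = tc$t0, t_mult = tc$t_mult)
      st <- adamw_step(model$params, grads, opt, lr_now, tc$weight_decay,
                       frozen = frozen)
      model$params <- st$params
      opt <- st$state
      ep_lf <- ep_lf + lf * length(b)
      ep_lc <- ep_lc + lc * length(b)
      ep_lt <- ep_lt + lt * length(b)
    }
    n_tr <- length(train_idx)
    val_pred <- hybrid_predict(model, ids[val_idx, , drop = FALSE],
                               feats[val_idx, , drop = FALSE],
                               branches = tc$branches)
    val_auroc <- auroc(val_pred$prob, y[val_idx])
    val_c <- c_index(val_pred$hazard, tte[val_idx], y[val_idx])
    composite <- (val_auroc + val_c) / 2
    history[[epoch]] <- data.frame(
      epoch = epoch, loss_focal = ep_lf / n_tr, loss_cox = ep_lc / n_tr,
      loss_total = ep_lt / n_tr, val_auroc = val_auroc, val_c_index = val_c,
      composite = composite,
      sigma_focal = exp(model$params$log_sigma_focal),
      sigma_cox = exp(model$params$log_sigma_cox),
      sigma_frozen = length(frozen) > 0,
      lr = cosine_warm_restart_lr(epoch - 1, tc$lr, t0 = tc$t0,
                                  t_mult = tc$t_mult))
    if (verbose) {
      message(sprintf(
        "epoch %02d  Lf %.4f  Lc %.4f  val AUROC %.3f  C %.3f  sigma %.3f/%.3f",
        epoch, ep_lf / n_tr, ep_lc / n_tr, val_auroc, val_c,
        exp(model$params$log_sigma_focal), exp(model$params$log_sigma_cox)))
    }
    if (composite > best$score + 1e-12) {
      best <- list(score = composite, epoch = epoch, params = model$params)
      patience_left <- tc$patience
    } else if (epoch >= tc$min_epochs) {
      patience_left <- patience_left - 1
      if (patience_left <= 0) break
    }
  }
  history <- do.call(rbind, history)
  final_model <- model
  final_model$params <- best$params
  out <- list(model = final_model, last_model = model, history = history,
              best_epoch = best$epoch, config = config, train_config = tc,
              sigma_init = sigma_init, ids = ids, split = prepared$split,
              tokenizer_path = tokenizer$path)
  class(out) <- "trained_model"
  out
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model: %d epochs run, best epoch %d (val AUROC %.3f, C %.3f)\n",
              nrow(x$history), x$best_epoch,
              x$history$val_auroc[x$best_epoch],
              x$history$val_c_index[x$best_epoch]))
  invisible(x)
}

#' Select the best epoch from a training history
#'
#' Maximizes the unweighted mean of validation AUROC and C-index; exact
#' ties resolve to the earliest epoch.
#'
#' @param history data.frame with columns `val_auroc` and `val_c_index`
#'   (one row per validated epoch).
#' @return The selected epoch (row index).
#' @export
#' @examples
#' select_model(data.frame(val_auroc = c(.70, .72, .71),
#'                         val_c_index = c(.68, .69, .70)))  # 2
select_model <- function(history) {
  if (nrow(history) < 1) stop("at least one validated epoch is required")
  score <- (history$val_auroc + history$val_c_index) / 2
  which.max(score)  # which.max returns the first maximum: earliest epoch
}

#' Save a model checkpoint
#'
#' Single-file archive holding the weights together with a manifest
#' (configuration hash, seed, epoch, package version).
#'
#' @param model A `hybrid_model` (or the `model` element of a
#'   `trained_model`).
#' @param path Destination file.
#' @param epoch Optional epoch tag for the manifest.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path, epoch = NA_integer_) {
  manifest <- list(
    config_hash = config_digest(model$config),
    seed = model$config$seed, epoch = epoch,
    package_version = as.character(utils::packageVersion("riskfusion")),
    saved_at = format(Sys.time(), tz = "UTC")
  )
  saveRDS(list(params = model$params, config = model$config,
               vocab_size = model$vocab_size, n_features = model$n_features,
               manifest = manifest), path)
  invisible(path)
}

#' Load a model checkpoint saved by [save_checkpoint()]
#'
#' @param path Checkpoint file.
#' @return List with `params`, `config`, `manifest` (and shape metadata).
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("configuration error: checkpoint not found: ",
                               path)
  ck <- readRDS(path)
  class(ck$config) <- "model_config"
  ck
}

config_digest <- function(config) {
  cfg <- unclass(config)
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  # stable polynomial rolling hash; avoids a digest dependency
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}
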