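# AdamW (decoupled weight decay) with global gradient-norm clipping and a
# cosine-annealing-with-warm-restarts learning-rate schedule.

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0)
}

# parameters whose names match these patterns are excluded from weight decay
.no_decay_pattern <- "(_b$|\\.b$|ln.*_g$|ln.*_b$|^log_|\\.b[0-9]$|bq$|bk$|bv$|bo$|b1$|b2$)"

adamw_step <- function(params, grads, state, lr, weight_decay = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       frozen = character(0)) {
  state$t <- state$t + 1
  t <- state$t
  for (nm in names(grads)) {
    if (nm %in% frozen) next
    gnm <- grads[[nm]]
    if (is.null(gnm)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    upd <- mhat / (sqrt(vhat) + eps)
    if (!grepl(.no_decay_pattern, nm)) {
      upd <- upd + weight_decay * params[[nm]]
    }
    params[[nm]] <- params[[nm]] - lr * upd
  }
  list(params = params, state = state)
}

#' Cosine-annealing learning rate with warm restarts
#'
#' Restart cycles start at length `t0` epochs and grow by `t_mult` at each
#' restart; within a cycle the rate decays from `lr0` to `lr_min` along a
#' half cosine.
#'
#' @param epoch Fractional epoch position (0-based).
#' @param lr0 Initial learning rate.
#' @param lr_min Floor learning rate (default 0).
#' @param t0 First cycle length in epochs.
#' @param t_mult Cycle length multiplier.
#' @return Learning rate at `epoch`.
#' @export
cosine_warm_restart_lr <- function(epoch, lr0 = 3e-4, lr_min = 0,
                                   t0 = 10, t_mult = 2) {
  t_i <- t0
  t_cur <- epoch
  while (t_cur >= t_i) {
    t_cur <- t_cur - t_i
    t_i <- t_i * t_mult
  }
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * t_cur / t_i))
}
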