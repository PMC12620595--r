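# The dual-branch hybrid model: transformer text encoder, MLP structured
# branch, linear alignment projections, stacked multi-head self-attention
# fusion with residual connections and layer normalization, and independent
# classification / log-hazard heads with temperature scaling.

#' Hybrid model configuration
#'
#' @param text_mode `"tiny"` (seeded random initialization; the default so
#'   the package builds and tests without any external weights) or
#'   `"pretrained"` together with `pretrained_path` pointing at a checkpoint
#'   saved by [save_checkpoint()].
#' @param max_tokens Token budget for the text branch (default 128).
#' @param d_text Text embedding width (default 64).
#' @param n_text_layers,n_text_heads Transformer depth / heads (default 2/4).
#' @param ffn_mult Feed-forward expansion factor inside the encoder blocks.
#' @param mlp_widths Hidden widths of the structured branch (default
#'   `c(64, 64)`).
#' @param dropout Dropout rate for MLP and feed-forward hidden layers.
#' @param d_fusion Fusion width; must be divisible by `n_fusion_heads`.
#' @param n_fusion_layers,n_fusion_heads Fusion attention stack (default 2/4).
#' @param pool `"cls"` (first-sentinel hidden state, default) or `"mean"`
#'   over non-pad positions.
#' @param temperature Initial temperature (learnable scalar, default 1).
#' @param learn_temperature Train the temperature jointly (default TRUE).
#' @param pretrained_path Optional checkpoint path for the text branch.
#' @param seed Seed for weight initialization.
#' @return Object of class `model_config`.
#' @export
model_config <- function(text_mode = c("tiny", "pretrained"),
                         max_tokens = 128, d_text = 64, n_text_layers = 2,
                         n_text_heads = 4, ffn_mult = 2,
                         mlp_widths = c(64, 64), dropout = 0.2,
                         d_fusion = 64, n_fusion_layers = 2,
                         n_fusion_heads = 4, pool = c("cls", "mean"),
                         temperature = 1, learn_temperature = TRUE,
                         pretrained_path = NULL, seed = 1) {
  text_mode <- match.arg(text_mode)
  pool <- match.arg(pool)
  if (temperature <= 0) stop("configuration error: temperature must be > 0")
  if (d_text %% n_text_heads != 0) {
    stop("configuration error: d_text must be divisible by n_text_heads")
  }
  if (d_fusion %% n_fusion_heads != 0) {
    stop("configuration error: d_fusion must be divisible by n_fusion_heads")
  }
  if (text_mode == "pretrained" &&
      (is.null(pretrained_path) || !file.exists(pretrained_path))) {
    stop("configuration error: pretrained mode requires an existing ",
         "checkpoint path")
  }
  structure(list(
    text_mode = text_mode, max_tokens = as.integer(max_tokens),
    d_text = as.integer(d_text), n_text_layers = as.integer(n_text_layers),
    n_text_heads = as.integer(n_text_heads), ffn_mult = ffn_mult,
    mlp_widths = as.integer(mlp_widths), dropout = dropout,
    d_fusion = as.integer(d_fusion),
    n_fusion_layers = as.integer(n_fusion_layers),
    n_fusion_heads = as.integer(n_fusion_heads), pool = pool,
    temperature = temperature, learn_temperature = isTRUE(learn_temperature),
    pretrained_path = pretrained_path, seed = as.integer(seed),
    pad_id = 1L
  ), class = "model_config")
}

#' Initialize a hybrid model
#'
#' @param config A [model_config()].
#' @param vocab_size Tokenizer vocabulary size.
#' @param n_features Structured feature count.
#' @return Object of class `hybrid_model` with `params` (named list of
#'   arrays, including the loss uncertainty parameters on the log scale)
#'   and the `config`.
#' @export
init_model <- function(config, vocab_size, n_features) {
  stopifnot(inherits(config, "model_config"))
  set.seed(config$seed)
  d <- config$d_text
  f <- config$d_fusion
  p <- list()
  p$tok_emb <- nn_init_matrix(vocab_size, d)
  p$pos_emb <- nn_init_matrix(config$max_tokens, d)
  for (i in seq_len(config$n_text_layers)) {
    pre <- sprintf("tl%d.", i)
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- rep(0, d)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      p[[paste0(pre, nm)]] <- nn_init_matrix(d, d)
    }
    for (nm in c("bq", "bk", "bv", "bo")) {
      p[[paste0(pre, nm)]] <- rep(0, d)
    }
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    dff <- as.integer(d * config$ffn_mult)
    p[[paste0(pre, "W1")]] <- nn_init_matrix(d, dff)
    p[[paste0(pre, "b1")]] <- rep(0, dff)
    p[[paste0(pre, "W2")]] <- nn_init_matrix(dff, d)
    p[[paste0(pre, "b2")]] <- rep(0, d)
  }
  p$lnf_g <- rep(1, d)
  p$lnf_b <- rep(0, d)
  widths <- c(n_features, config$mlp_widths)
  for (j in seq_along(config$mlp_widths)) {
    pre <- sprintf("sl%d.", j)
    p[[paste0(pre, "W")]] <- nn_init_matrix(widths[j], widths[j + 1],
                                            sd = sqrt(2 / widths[j]))
    p[[paste0(pre, "b")]] <- rep(0, widths[j + 1])
  }
  p$fus_text.W <- nn_init_matrix(d, f, sd = sqrt(1 / d))
  p$fus_text.b <- rep(0, f)
  d_s <- utils::tail(config$mlp_widths, 1)
  p$fus_struct.W <- nn_init_matrix(d_s, f, sd = sqrt(1 / d_s))
  p$fus_struct.b <- rep(0, f)
  for (i in seq_len(config$n_fusion_layers)) {
    pre <- sprintf("fl%d.", i)
    for (nm in c("Wq", "Wk", "Wv", "Wo")) {
      p[[paste0(pre, nm)]] <- nn_init_matrix(f, f)
    }
    for (nm in c("bq", "bk", "bv", "bo")) {
      p[[paste0(pre, nm)]] <- rep(0, f)
    }
    p[[paste0(pre, "ln_g")]] <- rep(1, f)
    p[[paste0(pre, "ln_b")]] <- rep(0, f)
  }
  p$clf.w <- rnorm(f, 0, sqrt(1 / f))
  p$clf.b <- 0
  p$haz.w <- rnorm(f, 0, sqrt(1 / f))
  p$haz.b <- 0
  p$log_temp <- log(config$temperature)
  p$log_sigma_focal <- 0
  p$log_sigma_cox <- 0
  if (config$text_mode == "pretrained") {
    ck <- load_checkpoint(config$pretrained_path)
    text_names <- grep("^(tok_emb|pos_emb|tl[0-9]+\\.|lnf_)", names(ck$params),
                       value = TRUE)
    for (nm in text_names) {
      if (!identical(dim2(p[[nm]]), dim2(ck$params[[nm]]))) {
        stop("configuration error: pretrained checkpoint shape mismatch for ",
             nm)
      }
      p[[nm]] <- ck$params[[nm]]
    }
  }
  structure(list(params = p, config = config,
                 vocab_size = as.integer(vocab_size),
                 n_features = as.integer(n_features)),
            class = "hybrid_model")
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' @export
print.hybrid_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("hybrid_model: %s text encoder (%d layers, width %d), MLP %s, fusion %dx%d heads; %d parameters\n",
              x$config$text_mode, x$config$n_text_layers, x$config$d_text,
              paste(x$config$mlp_widths, collapse = "-"),
              x$config$n_fusion_layers, x$config$n_fusion_heads, n_par))
  invisible(x)
}

mha_weights <- function(params, pre) {
  list(Wq = params[[paste0(pre, "Wq")]], bq = params[[paste0(pre, "bq")]],
       Wk = params[[paste0(pre, "Wk")]], bk = params[[paste0(pre, "bk")]],
       Wv = params[[paste0(pre, "Wv")]], bv = params[[paste0(pre, "bv")]],
       Wo = params[[paste0(pre, "Wo")]], bo = params[[paste0(pre, "bo")]])
}

# ---- text branch ----------------------------------------------------------

text_encoder_fwd <- function(params, cfg, ids, train = FALSE) {
  B <- nrow(ids)
  T <- ncol(ids)
  if (max(ids) > nrow(params$tok_emb)) {
    stop("input error: token id exceeds vocabulary size")
  }
  id_vec <- as.vector(t(ids))                 # example-major ordering
  X <- params$tok_emb[id_vec, , drop = FALSE] +
    params$pos_emb[rep(seq_len(T), B), , drop = FALSE]
  valid <- ids != cfg$pad_id
  valid[, 1] <- TRUE                          # sentinel always attends
  layers <- vector("list", cfg$n_text_layers)
  for (i in seq_len(cfg$n_text_layers)) {
    pre <- sprintf("tl%d.", i)
    lc <- list(X_in = X)
    ln1 <- layernorm_fwd(X, params[[paste0(pre, "ln1_g")]],
                         params[[paste0(pre, "ln1_b")]])
    att <- mha_fwd(ln1$Y, mha_weights(params, pre), B, T,
                   cfg$n_text_heads, valid)
    X <- X + att$Y
    lc$ln1 <- ln1
    lc$att <- att
    lc$X_mid <- X
    ln2 <- layernorm_fwd(X, params[[paste0(pre, "ln2_g")]],
                         params[[paste0(pre, "ln2_b")]])
    H1 <- linear_fwd(ln2$Y, params[[paste0(pre, "W1")]],
                     params[[paste0(pre, "b1")]])
    A1 <- relu_fwd(H1)
    dr <- dropout_fwd(A1, cfg$dropout, train)
    F1 <- linear_fwd(dr$Y, params[[paste0(pre, "W2")]],
                     params[[paste0(pre, "b2")]])
    X <- X + F1
    lc$ln2 <- ln2
    lc$H1 <- H1
    lc$A1 <- A1
    lc$drop <- dr
    layers[[i]] <- lc
  }
  lnf <- layernorm_fwd(X, params$lnf_g, params$lnf_b)
  if (cfg$pool == "cls") {
    vec <- lnf$Y[(seq_len(B) - 1) * T + 1, , drop = FALSE]
  } else {
    counts <- rowSums(valid)
    vm <- matrix(as.numeric(t(valid)), ncol = 1)
    vec <- rowsum(lnf$Y * as.vector(vm), rep(seq_len(B), each = T)) / counts
  }
  list(vec = vec, layers = layers, lnf = lnf, valid = valid, B = B, T = T,
       id_vec = id_vec)
}

text_encoder_bwd <- function(params, cfg, cache, dvec) {
  B <- cache$B
  T <- cache$T
  g <- list()
  n_rows <- B * T
  d <- ncol(dvec)
  dX <- matrix(0, n_rows, d)
  if (cfg$pool == "cls") {
    dX[(seq_len(B) - 1) * T + 1, ] <- dvec
  } else {
    counts <- rowSums(cache$valid)
    dX <- dvec[rep(seq_len(B), each = T), , drop = FALSE] / counts[rep(seq_len(B), each = T)]
    dX <- dX * as.vector(t(cache$valid))
  }
  lb <- layernorm_bwd(cache$lnf, params$lnf_g, dX)
  g$lnf_g <- lb$dg
  g$lnf_b <- lb$db
  dX <- lb$dX
  for (i in rev(seq_len(cfg$n_text_layers))) {
    pre <- sprintf("tl%d.", i)
    lc <- cache$layers[[i]]
    # feed-forward sublayer
    l2 <- linear_bwd(lc$drop$Y, params[[paste0(pre, "W2")]], dX)
    g[[paste0(pre, "W2")]] <- l2$dW
    g[[paste0(pre, "b2")]] <- l2$db
    dA1 <- dropout_bwd(l2$dX, lc$drop$mask)
    dH1 <- relu_bwd(lc$H1, dA1)
    l1 <- linear_bwd(lc$ln2$Y, params[[paste0(pre, "W1")]], dH1)
    g[[paste0(pre, "W1")]] <- l1$dW
    g[[paste0(pre, "b1")]] <- l1$db
    lb2 <- layernorm_bwd(lc$ln2, params[[paste0(pre, "ln2_g")]], l1$dX)
    g[[paste0(pre, "ln2_g")]] <- lb2$dg
    g[[paste0(pre, "ln2_b")]] <- lb2$db
    dX <- dX + lb2$dX
    # attention sublayer
    ab <- mha_bwd(lc$ln1$Y, mha_weights(params, pre), lc$att, dX, B, T,
                  cfg$n_text_heads)
    for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")) {
      g[[paste0(pre, nm)]] <- ab[[paste0("d", nm)]]
    }
    lb1 <- layernorm_bwd(lc$ln1, params[[paste0(pre, "ln1_g")]], ab$dX)
    g[[paste0(pre, "ln1_g")]] <- lb1$dg
    g[[paste0(pre, "ln1_b")]] <- lb1$db
    dX <- dX + lb1$dX
  }
  g$tok_emb <- matrix(0, nrow(params$tok_emb), d)
  acc <- rowsum(dX, cache$id_vec)
  g$tok_emb[as.integer(rownames(acc)), ] <- acc
  g$pos_emb <- matrix(0, nrow(params$pos_emb), d)
  pos_acc <- rowsum(dX, rep(seq_len(T), B))
  g$pos_emb[seq_len(T), ] <- pos_acc
  g
}

# ---- structured branch ----------------------------------------------------

struct_encoder_fwd <- function(params, cfg, feats, train = FALSE) {
  X <- feats
  layers <- vector("list", length(cfg$mlp_widths))
  for (j in seq_along(cfg$mlp_widths)) {
    pre <- sprintf("sl%d.", j)
    H <- linear_fwd(X, params[[paste0(pre, "W")]], params[[paste0(pre, "b")]])
    A <- relu_fwd(H)
    dr <- dropout_fwd(A, cfg$dropout, train)
    layers[[j]] <- list(X_in = X, H = H, drop = dr)
    X <- dr$Y
  }
  list(vec = X, layers = layers)
}

struct_encoder_bwd <- function(params, cfg, cache, dvec) {
  g <- list()
  dX <- dvec
  for (j in rev(seq_along(cfg$mlp_widths))) {
    pre <- sprintf("sl%d.", j)
    lc <- cache$layers[[j]]
    dA <- dropout_bwd(dX, lc$drop$mask)
    dH <- relu_bwd(lc$H, dA)
    lb <- linear_bwd(lc$X_in, params[[paste0(pre, "W")]], dH)
    g[[paste0(pre, "W")]] <- lb$dW
    g[[paste0(pre, "b")]] <- lb$db
    dX <- lb$dX
  }
  g
}

# ---- fusion and heads -----------------------------------------------------

fusion_fwd <- function(params, cfg, text_vec, struct_vec) {
  B <- nrow(text_vec)
  tp <- linear_fwd(text_vec, params$fus_text.W, params$fus_text.b)
  sp <- linear_fwd(struct_vec, params$fus_struct.W, params$fus_struct.b)
  # interleave into a 2-token sequence per example
  X <- matrix(0, 2 * B, cfg$d_fusion)
  X[seq(1, 2 * B, 2), ] <- tp
  X[seq(2, 2 * B, 2), ] <- sp
  layers <- vector("list", cfg$n_fusion_layers)
  for (i in seq_len(cfg$n_fusion_layers)) {
    pre <- sprintf("fl%d.", i)
    att <- mha_fwd(X, mha_weights(params, pre), B, 2L, cfg$n_fusion_heads)
    Z <- X + att$Y
    ln <- layernorm_fwd(Z, params[[paste0(pre, "ln_g")]],
                        params[[paste0(pre, "ln_b")]])
    layers[[i]] <- list(X_in = X, att = att, ln = ln)
    X <- ln$Y
  }
  fused <- (X[seq(1, 2 * B, 2), , drop = FALSE] +
              X[seq(2, 2 * B, 2), , drop = FALSE]) / 2
  list(fused = fused, layers = layers, tp = tp, sp = sp, B = B)
}

fusion_bwd <- function(params, cfg, cache, text_vec, struct_vec, dfused) {
  B <- cache$B
  g <- list()
  dX <- matrix(0, 2 * B, cfg$d_fusion)
  dX[seq(1, 2 * B, 2), ] <- dfused / 2
  dX[seq(2, 2 * B, 2), ] <- dfused / 2
  for (i in rev(seq_len(cfg$n_fusion_layers))) {
    pre <- sprintf("fl%d.", i)
    lc <- cache$layers[[i]]
    lb <- layernorm_bwd(lc$ln, params[[paste0(pre, "ln_g")]], dX)
    g[[paste0(pre, "ln_g")]] <- lb$dg
    g[[paste0(pre, "ln_b")]] <- lb$db
    ab <- mha_bwd(lc$X_in, mha_weights(params, pre), lc$att, lb$dX, B, 2L,
                  cfg$n_fusion_heads)
    for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo")) {
      g[[paste0(pre, nm)]] <- ab[[paste0("d", nm)]]
    }
    dX <- lb$dX + ab$dX
  }
  dtp <- dX[seq(1, 2 * B, 2), , drop = FALSE]
  dsp <- dX[seq(2, 2 * B, 2), , drop = FALSE]
  lt <- linear_bwd(text_vec, params$fus_text.W, dtp)
  ls <- linear_bwd(struct_vec, params$fus_struct.W, dsp)
  g$fus_text.W <- lt$dW
  g$fus_text.b <- lt$db
  g$fus_struct.W <- ls$dW
  g$fus_struct.b <- ls$db
  list(grads = g, dtext_vec = lt$dX, dstruct_vec = ls$dX)
}

#' Apply temperature scaling to a raw logit
#'
#' @param raw Raw (pre-temperature) logit.
#' @param temperature Temperature `T > 0`; the scaled logit is `raw / T`.
#' @return Scaled logit.
#' @export
#' @examples
#' apply_temperature(2, 2)  # 1
apply_temperature <- function(raw, temperature) {
  if (temperature <= 0) stop("configuration error: temperature must be > 0")
  raw / temperature
}

# ---- full forward / backward ---------------------------------------------

hybrid_fwd <- function(model, ids, feats, train = FALSE,
                       branches = c("text", "structured")) {
  params <- model$params
  cfg <- model$config
  if (ncol(feats) != model$n_features) {
    stop("input error: feature length mismatch")
  }
  B <- nrow(ids)
  use_text <- "text" %in% branches
  use_struct <- "structured" %in% branches
  tc <- NULL
  sc <- NULL
  tv <- matrix(0, B, cfg$d_text)
  sv <- matrix(0, B, utils::tail(cfg$mlp_widths, 1))
  if (use_text) {
    tc <- text_encoder_fwd(params, cfg, ids, train)
    tv <- tc$vec
  }
  if (use_struct) {
    sc <- struct_encoder_fwd(params, cfg, feats, train)
    sv <- sc$vec
  }
  fc <- fusion_fwd(params, cfg, tv, sv)
  raw <- as.vector(fc$fused %*% params$clf.w) + params$clf.b
  temp <- exp(params$log_temp)
  logit <- apply_temperature(raw, temp)
  hazard <- as.vector(fc$fused %*% params$haz.w) + params$haz.b
  list(logit = logit, hazard = hazard, raw = raw,
       prob = stats::plogis(logit),
       cache = list(text = tc, struct = sc, fusion = fc, tv = tv, sv = sv,
                    temp = temp, branches = branches))
}

hybrid_bwd <- function(model, fwd, dlogit, dhazard) {
  params <- model$params
  cfg <- model$config
  ca <- fwd$cache
  g <- list()
  fused <- ca$fusion$fused
  draw <- dlogit / ca$temp
  g$clf.w <- as.vector(crossprod(fused, draw))
  g$clf.b <- sum(draw)
  g$haz.w <- as.vector(crossprod(fused, dhazard))
  g$haz.b <- sum(dhazard)
  g$log_temp <- if (cfg$learn_temperature)
    -sum(dlogit * fwd$logit) else 0
  dfused <- outer(draw, params$clf.w) + outer(dhazard, params$haz.w)
  fb <- fusion_bwd(params, cfg, ca$fusion, ca$tv, ca$sv, dfused)
  g <- c(g, fb$grads)
  if ("text" %in% ca$branches) {
    g <- c(g, text_encoder_bwd(params, cfg, ca$text, fb$dtext_vec))
  }
  if ("structured" %in% ca$branches) {
    g <- c(g, struct_encoder_bwd(params, cfg, ca$struct, fb$dstruct_vec))
  }
  g
}

# ---- user-facing encode / predict wrappers (evaluation mode) --------------

#' Encode narratives with the text branch
#'
#' @param model A `hybrid_model`.
#' @param ids Token id matrix (one row per narrative).
#' @return Matrix of text representation vectors.
#' @export
encode_text <- function(model, ids) {
  text_encoder_fwd(model$params, model$config, ids, train = FALSE)$vec
}

#' Encode structured features with the MLP branch
#'
#' @param model A `hybrid_model`.
#' @param feats Scaled feature matrix.
#' @return Matrix of structured representation vectors.
#' @export
encode_structured <- function(model, feats) {
  if (ncol(feats) != model$n_features) {
    stop("input error: feature length mismatch")
  }
  struct_encoder_fwd(model$params, model$config, feats, train = FALSE)$vec
}

#' Fuse branch representations through the attention stack
#'
#' @param model A `hybrid_model`.
#' @param text_vec,struct_vec Branch representation matrices (same rows).
#' @return Matrix of fused representations (width `d_fusion`).
#' @export
fuse_and_attend <- function(model, text_vec, struct_vec) {
  fusion_fwd(model$params, model$config, text_vec, struct_vec)$fused
}

#' Predict classification logits and log hazards for episodes
#'
#' Full evaluation-mode forward pass.
#'
#' @param model A `hybrid_model`.
#' @param ids Token id matrix.
#' @param feats Scaled structured feature matrix.
#' @param branches Branch ablation: subset of `c("text", "structured")`.
#' @param batch_size Forward-pass batch size.
#' @return data.frame with `logit`, `prob` and `hazard` per episode.
#' @export
hybrid_predict <- function(model, ids, feats,
                           branches = c("text", "structured"),
                           batch_size = 256) {
  n <- nrow(ids)
  out <- vector("list", ceiling(n / batch_size))
  for (k in seq_along(out)) {
    idx <- ((k - 1) * batch_size + 1):min(k * batch_size, n)
    fw <- hybrid_fwd(model, ids[idx, , drop = FALSE],
                     feats[idx, , drop = FALSE], train = FALSE,
                     branches = branches)
    out[[k]] <- data.frame(logit = fw$logit, prob = fw$prob,
                           hazard = fw$hazard)
  }
  do.call(rbind, out)
}
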