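# Minimal neural-network primitives with explicit forward and backward
# passes (no autodiff dependency exists for R in this stack).  All layers
# operate on row-major matrices; a token batch is stored as a (B*T) x d
# matrix with example b occupying rows ((b-1)*T + 1):(b*T).  Analytic
# gradients are finite-difference-checked in the test suite.

nn_init_matrix <- function(nr, nc, sd = 0.02) {
  matrix(rnorm(nr * nc, 0, sd), nr, nc)
}

linear_fwd <- function(X, W, b) {
  sweep(X %*% W, 2, b, `+`)
}

linear_bwd <- function(X, W, dY) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

relu_fwd <- function(X) pmax(X, 0)

relu_bwd <- function(X, dY) dY * (X > 0)

dropout_fwd <- function(X, p, train) {
  if (!train || p <= 0) return(list(Y = X, mask = NULL))
  mask <- matrix(rbinom(length(X), 1, 1 - p), nrow(X), ncol(X)) / (1 - p)
  list(Y = X * mask, mask = mask)
}

dropout_bwd <- function(dY, mask) {
  if (is.null(mask)) dY else dY * mask
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  Y <- sweep(xhat, 2, g, `*`)
  Y <- sweep(Y, 2, b, `+`)
  list(Y = Y, xhat = xhat, inv_sd = inv_sd)
}

layernorm_bwd <- function(cache, g, dY) {
  xhat <- cache$xhat
  inv_sd <- cache$inv_sd
  D <- ncol(xhat)
  dxhat <- sweep(dY, 2, g, `*`)
  # dX = inv_sd * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dX <- inv_sd * (dxhat - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# Multi-head self-attention over a (B*T) x d batch.  `valid` is a B x T
# logical matrix; invalid (padding) positions are masked out as keys.
mha_fwd <- function(X, W, B, T, H, valid = NULL) {
  d <- ncol(X)
  dh <- d %/% H
  Q <- linear_fwd(X, W$Wq, W$bq)
  K <- linear_fwd(X, W$Wk, W$bk)
  V <- linear_fwd(X, W$Wv, W$bv)
  Ctx <- matrix(0, nrow(X), d)
  P_list <- vector("list", B * H)
  scale <- 1 / sqrt(dh)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    keymask <- if (is.null(valid)) NULL else which(!valid[b, ])
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) * scale
      if (length(keymask)) S[, keymask] <- -1e30
      P <- softmax_rows(S)
      P_list[[(b - 1) * H + h]] <- P
      Ctx[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
    }
  }
  Y <- linear_fwd(Ctx, W$Wo, W$bo)
  list(Y = Y, Q = Q, K = K, V = V, Ctx = Ctx, P = P_list)
}

mha_bwd <- function(X, W, cache, dY, B, T, H) {
  d <- ncol(X)
  dh <- d %/% H
  scale <- 1 / sqrt(dh)
  lo <- linear_bwd(cache$Ctx, W$Wo, dY)
  dCtx <- lo$dX
  dQ <- matrix(0, nrow(X), d)
  dK <- matrix(0, nrow(X), d)
  dV <- matrix(0, nrow(X), d)
  for (b in seq_len(B)) {
    rows <- ((b - 1) * T + 1):(b * T)
    for (h in seq_len(H)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      P <- cache$P[[(b - 1) * H + h]]
      dCtx_h <- dCtx[rows, cols, drop = FALSE]
      Vh <- cache$V[rows, cols, drop = FALSE]
      dP <- tcrossprod(dCtx_h, Vh)
      dV[rows, cols] <- crossprod(P, dCtx_h)
      dS <- (dP - rowSums(dP * P)) * P
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] * scale
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) *
        scale
    }
  }
  lq <- linear_bwd(X, W$Wq, dQ)
  lk <- linear_bwd(X, W$Wk, dK)
  lv <- linear_bwd(X, W$Wv, dV)
  list(dX = lq$dX + lk$dX + lv$dX + 0,  # residual added by caller
       dWq = lq$dW, dbq = lq$db, dWk = lk$dW, dbk = lk$db,
       dWv = lv$dW, dbv = lv$db, dWo = lo$dW, dbo = lo$db)
}

# global gradient-norm clipping over a flat list of gradient arrays
clip_gradients <- function(grads, max_norm = 1) {
  total <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(total) && total > max_norm && total > 0) {
    grads <- lapply(grads, function(g) g * (max_norm / total))
  }
  grads
}
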