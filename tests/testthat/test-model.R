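test_that("configuration invariants are enforced", {
  expect_error(model_config(temperature = 0), "temperature")
  expect_error(model_config(d_fusion = 30, n_fusion_heads = 4), "divisible")
  expect_error(model_config(d_text = 30, n_text_heads = 4), "divisible")
  expect_error(model_config(text_mode = "pretrained",
                            pretrained_path = "/no/such.ckpt"), "checkpoint")
})

test_that("text encoder obeys the shape contract and is deterministic in eval mode", {
  cfg <- tiny_model_config()
  m <- init_model(cfg, vocab_size = 30, n_features = 5)
  ids <- matrix(sample(2:30, 3 * 12, TRUE), 3, 12)
  ids[, 1] <- 3
  v1 <- encode_text(m, ids)
  expect_equal(dim(v1), c(3, cfg$d_text))
  expect_identical(v1, encode_text(m, ids))
  expect_error(encode_text(m, matrix(31, 1, 12)), "vocabulary")
})

test_that("distinct token sequences give distinct text representations", {
  cfg <- tiny_model_config(seed = 9)
  m <- init_model(cfg, vocab_size = 50, n_features = 5)
  set.seed(2)
  ids <- matrix(sample(2:50, 100 * 12, TRUE), 100, 12)
  ids[, 1] <- 3
  vecs <- encode_text(m, ids)
  expect_equal(anyDuplicated(round(vecs, 10)), 0)
})

test_that("padding positions do not influence the representation", {
  cfg <- tiny_model_config()
  m <- init_model(cfg, vocab_size = 30, n_features = 5)
  ids_a <- matrix(1L, 1, 12)
  ids_a[1, 1:4] <- c(3L, 10L, 11L, 4L)
  ids_b <- ids_a
  # padding ids are identical (id 1); representation must only depend on
  # the non-pad prefix, so appending more pads changes nothing
  short <- encode_text(m, ids_a[, 1:6, drop = FALSE])
  long <- encode_text(m, ids_a)
  expect_equal(short, long, tolerance = 1e-10)
})

test_that("structured encoder is a plain ReLU MLP", {
  cfg <- model_config(mlp_widths = 2, dropout = 0, seed = 1,
                      d_fusion = 8, n_fusion_heads = 2)
  m <- init_model(cfg, vocab_size = 10, n_features = 2)
  m$params$sl1.W <- diag(2)
  m$params$sl1.b <- c(0, 0)
  expect_equal(unname(encode_structured(m, matrix(c(-1, 2), 1))),
               matrix(c(0, 2), 1))
  expect_equal(unname(encode_structured(m, matrix(0, 1, 2))),
               matrix(0, 1, 2))
  expect_error(encode_structured(m, matrix(0, 1, 3)), "length mismatch")
})

test_that("fusion keeps identical tokens identical and matches the empty-stack mean", {
  cfg <- tiny_model_config()
  m <- init_model(cfg, vocab_size = 10, n_features = 5)
  # force the two branch projections to coincide
  m$params$fus_struct.W <- m$params$fus_text.W[1:5, ] * 0
  m$params$fus_text.W <- rbind(m$params$fus_struct.W, matrix(0, 3, 8))
  tv <- matrix(rnorm(2 * 8), 2, 8)
  sv <- matrix(rnorm(2 * 5), 2, 5)
  fc <- riskfusion:::fusion_fwd(m$params, m$config, tv, sv)
  # both projections are zero here: identical tokens stay identical through
  # every attention layer (softmax over identical keys is uniform)
  expect_equal(fc$layers[[2]]$ln$Y[1, ], fc$layers[[2]]$ln$Y[2, ])
  # empty attention stack: output is the mean of the two projections
  cfg0 <- model_config(max_tokens = 12, d_text = 8, n_text_layers = 1,
                       n_text_heads = 2, mlp_widths = c(6, 5), dropout = 0,
                       d_fusion = 8, n_fusion_layers = 0,
                       n_fusion_heads = 2, seed = 5)
  m0 <- init_model(cfg0, vocab_size = 10, n_features = 5)
  f0 <- fuse_and_attend(m0, tv, sv)
  tp <- sweep(tv %*% m0$params$fus_text.W, 2, m0$params$fus_text.b, `+`)
  sp <- sweep(sv %*% m0$params$fus_struct.W, 2, m0$params$fus_struct.b, `+`)
  expect_equal(f0, (tp + sp) / 2, tolerance = 1e-12)
  expect_equal(ncol(f0), cfg0$d_fusion)
})

test_that("temperature scaling behaves as a simple division with guards", {
  expect_equal(apply_temperature(2, 2), 1)
  expect_equal(apply_temperature(1.7, 1), 1.7)
  expect_equal(plogis(apply_temperature(50, 1e6)), 0.5, tolerance = 1e-4)
  expect_error(apply_temperature(1, 0), "temperature")
})

test_that("full forward pass is a pure function of weights and input", {
  cfg <- tiny_model_config()
  m <- init_model(cfg, vocab_size = 30, n_features = 5)
  ids <- matrix(sample(2:30, 4 * 12, TRUE), 4, 12)
  feats <- matrix(rnorm(20), 4, 5)
  f1 <- riskfusion:::hybrid_fwd(m, ids, feats, train = FALSE)
  f2 <- riskfusion:::hybrid_fwd(m, ids, feats, train = FALSE)
  expect_identical(f1$logit, f2$logit)
  expect_identical(f1$hazard, f2$hazard)
  expect_true(all(is.finite(c(f1$logit, f1$hazard))))
  expect_true(all(f1$prob > 0 & f1$prob < 1))
})

test_that("analytic gradients match finite differences across all parameters", {
  cfg <- tiny_model_config(seed = 13)
  m <- init_model(cfg, vocab_size = 20, n_features = 7)
  set.seed(31)
  ids <- matrix(sample(2:20, 4 * 12, TRUE), 4, 12)
  ids[, 1] <- 3
  ids[1, 9:12] <- 1
  feats <- matrix(rnorm(28), 4, 7)
  r1 <- rnorm(4)
  r2 <- rnorm(4)
  fobj <- function(params) {
    mm <- m
    mm$params <- params
    fw <- riskfusion:::hybrid_fwd(mm, ids, feats, train = FALSE)
    sum(fw$logit * r1) + sum(fw$hazard * r2)
  }
  fw <- riskfusion:::hybrid_fwd(m, ids, feats, train = FALSE)
  gr <- riskfusion:::hybrid_bwd(m, fw, r1, r2)
  for (nm in names(gr)) {
    p0 <- m$params[[nm]]
    pick <- if (length(p0) > 4) sample(length(p0), 4) else seq_along(p0)
    for (i in pick) {
      pp <- m$params
      pp[[nm]][i] <- p0[i] + 1e-5
      fp <- fobj(pp)
      pp[[nm]][i] <- p0[i] - 1e-5
      fm <- fobj(pp)
      num <- (fp - fm) / 2e-5
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("checkpoints round-trip and feed the pretrained text mode", {
  cfg <- tiny_model_config(seed = 21)
  m <- init_model(cfg, vocab_size = 25, n_features = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, epoch = 4)
  ck <- load_checkpoint(path)
  expect_equal(ck$manifest$epoch, 4)
  expect_identical(ck$params$tok_emb, m$params$tok_emb)
  cfg2 <- tiny_model_config(seed = 99)
  cfg2$text_mode <- "pretrained"
  cfg2$pretrained_path <- path
  m2 <- init_model(cfg2, vocab_size = 25, n_features = 5)
  # text-branch weights inherited, heads freshly initialized
  expect_identical(m2$params$tok_emb, m$params$tok_emb)
  expect_false(identical(m2$params$clf.w, m$params$clf.w))
  expect_error(load_checkpoint("/no/file.rds"), "not found")
})
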