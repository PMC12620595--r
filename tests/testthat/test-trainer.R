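test_that("model selection maximizes the AUROC/C composite with earliest-epoch ties", {
  h <- data.frame(val_auroc = c(0.70, 0.72, 0.71),
                  val_c_index = c(0.68, 0.69, 0.70))
  expect_equal(select_model(h), 2)
  expect_equal(select_model(h[1, , drop = FALSE]), 1)
  tie <- data.frame(val_auroc = c(0.70, 0.72), val_c_index = c(0.72, 0.70))
  expect_equal(select_model(tie), 1)
  expect_error(select_model(h[0, ]), "at least one")
})

test_that("cosine warm restarts anneal within cycles and restart on schedule", {
  lr0 <- 3e-4
  expect_equal(cosine_warm_restart_lr(0, lr0), lr0)
  # end of the first cycle decays to the floor, then restarts
  expect_lt(cosine_warm_restart_lr(9.99, lr0), 1e-6)
  expect_equal(cosine_warm_restart_lr(10, lr0), lr0)
  # second cycle is twice as long: its midpoint (epoch 20) matches the
  # first cycle's midpoint (epoch 5)
  expect_equal(cosine_warm_restart_lr(20, lr0),
               cosine_warm_restart_lr(5, lr0))
  expect_gt(cosine_warm_restart_lr(0.5, lr0),
            cosine_warm_restart_lr(5, lr0))
})

test_that("trailing batches below the risk-set floor merge into their predecessor", {
  b <- riskfusion:::batch_indices(1:150, 64, 64)
  expect_equal(lengths(b), c(64, 86))
  b2 <- riskfusion:::batch_indices(1:128, 64, 64)
  expect_equal(lengths(b2), c(64, 64))
  b3 <- riskfusion:::batch_indices(1:40, 64, 64)
  expect_equal(lengths(b3), 40)
})

make_tiny_prepared <- function(seed = 2) {
  co <- generate_cohort(cohort_spec(n_patients = 80, seed = seed,
                                    signal = 3))
  prepare_dataset(co, seed = seed)
}

tiny_train <- function(prep, epochs = 3, ...) {
  cfg <- model_config(max_tokens = 16, d_text = 8, n_text_layers = 1,
                      n_text_heads = 2, mlp_widths = c(8), dropout = 0.1,
                      d_fusion = 8, n_fusion_layers = 1, n_fusion_heads = 2,
                      seed = 5)
  tc <- train_config(epochs = epochs, batch_size = 64, seed = 9,
                     patience = epochs, ...)
  train_model(prep, cfg, tc)
}

test_that("training is deterministic: same seed and data give identical histories", {
  prep <- make_tiny_prepared()
  f1 <- tiny_train(prep, epochs = 2)
  f2 <- tiny_train(prep, epochs = 2)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("gradients flow to both branches and the uncertainty schedule is staged", {
  prep <- make_tiny_prepared()
  fit <- tiny_train(prep, epochs = 3, sigma_freeze_epochs = 2)
  cfg <- model_config(max_tokens = 16, d_text = 8, n_text_layers = 1,
                      n_text_heads = 2, mlp_widths = c(8), dropout = 0.1,
                      d_fusion = 8, n_fusion_layers = 1, n_fusion_heads = 2,
                      seed = 5)
  init <- init_model(cfg, vocab_size = length(load_tokenizer()$vocab),
                     n_features = ncol(prep$features))
  # both branches moved away from initialization after optimization
  expect_false(identical(fit$last_model$params$tok_emb, init$params$tok_emb))
  expect_false(identical(fit$last_model$params$sl1.W, init$params$sl1.W))
  # sigma frozen at exactly 1 through the freeze stage, adapting after
  expect_equal(fit$history$sigma_focal[1:2], c(1, 1))
  expect_equal(fit$history$sigma_cox[1:2], c(1, 1))
  expect_false(fit$history$sigma_focal[3] == 1 &&
                 fit$history$sigma_cox[3] == 1)
  expect_true(all(fit$history$sigma_frozen[1:2]))
  expect_false(fit$history$sigma_frozen[3])
})

test_that("early stopping halts after patience exhausts", {
  prep <- make_tiny_prepared()
  cfg <- model_config(max_tokens = 16, d_text = 8, n_text_layers = 1,
                      n_text_heads = 2, mlp_widths = c(8), dropout = 0,
                      d_fusion = 8, n_fusion_layers = 1, n_fusion_heads = 2,
                      seed = 5)
  # learning rate 0: validation score never improves after the first epoch,
  # so training must stop after exactly 1 + patience epochs once the
  # minimum-epoch floor is disabled
  tc <- train_config(epochs = 20, batch_size = 64, seed = 9, lr = 0,
                     patience = 3, min_epochs = 1)
  fit <- train_model(prep, cfg, tc)
  expect_equal(nrow(fit$history), 4)
  expect_equal(fit$best_epoch, 1)
  # with the floor in place, stopping waits until the floor is reached
  tc2 <- train_config(epochs = 20, batch_size = 64, seed = 9, lr = 0,
                      patience = 3, min_epochs = 6)
  fit2 <- train_model(prep, cfg, tc2)
  expect_equal(nrow(fit2$history), 8)
})

test_that("loss-mode ablations route gradients to a single head", {
  prep <- make_tiny_prepared()
  f_cox <- tiny_train(prep, epochs = 2, loss_mode = "cox_only",
                      weight_decay = 0)
  f_foc <- tiny_train(prep, epochs = 2, loss_mode = "focal_only",
                      weight_decay = 0)
  # with only the Cox objective, the classification head receives no
  # gradient (its weights stay at initialization) and vice versa
  vs <- length(load_tokenizer()$vocab)
  init <- init_model(f_cox$model$config, vocab_size = vs,
                     n_features = ncol(prep$features))
  expect_identical(f_cox$last_model$params$clf.w, init$params$clf.w)
  expect_false(identical(f_cox$last_model$params$haz.w, init$params$haz.w))
  expect_identical(f_foc$last_model$params$haz.w, init$params$haz.w)
  expect_false(identical(f_foc$last_model$params$clf.w, init$params$clf.w))
})
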