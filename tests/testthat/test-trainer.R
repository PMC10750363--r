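test_that("early stopping fires exactly after `patience` non-improving epochs", {
  losses <- c(1.0, 0.9, 0.91, 0.92, 0.93, 0.94, 0.95)
  fired_at <- vapply(seq_along(losses), function(e)
    early_stop_check(losses[1:e], patience = 5L), logical(1))
  expect_identical(fired_at, c(rep(FALSE, 6), TRUE))  # best at 2, fires at 7
  expect_false(early_stop_check(c(1, 0.9, 0.8, 0.7), patience = 5L))
  expect_false(early_stop_check(0.5, patience = 5L))  # shorter than patience
})

test_that("learning rate halves after exactly `patience` stagnant epochs and can compound", {
  lr0 <- 1e-3
  expect_equal(lr_schedule_step(c(0.6, 0.6, 0.6), rep(lr0, 3), 3L, lr0), lr0)
  expect_equal(lr_schedule_step(c(0.6, 0.6, 0.6, 0.6), rep(lr0, 4), 3L, lr0),
               lr0 / 2)
  expect_equal(lr_schedule_step(c(0.5, 0.6, 0.7, 0.8), rep(lr0, 4), 3L, lr0),
               lr0)
  # simulate a flat accuracy curve: two plateaus quarter the rate
  accs <- rep(0.6, 10); lrs <- numeric(10); lr <- lr0
  for (e in 1:10) {
    lrs[e] <- lr
    lr <- lr_schedule_step(accs[1:e], lrs[1:e], 3L, lr)
  }
  expect_equal(sort(unique(lrs), decreasing = TRUE), c(lr0, lr0 / 2, lr0 / 4))
  expect_equal(lrs[10], lr0 / 4)
})

test_that("a four-clip training set is fit to accuracy 1.0", {
  data <- four_clip_set()
  m <- build_model(arch_spec(c(1L, 1L, 1L, 1L), width_multiplier = 0.25),
                   seed = 7)
  fit <- train_fold(m, data, data,
                    train_config(learning_rate = 1e-3, batch_size = 4L,
                                 max_epochs = 50L, seed = 8))
  expect_lte(nrow(fit$history), 50L)
  expect_equal(fit$history$val_acc[nrow(fit$history)], 1.0)
  pred <- predict(fit$final_model, data$clips, type = "label")
  expect_identical(as.character(pred), data$labels)
})

test_that("training is reproducible and the checkpoint attains the best val loss", {
  data <- four_clip_set(seed = 9)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 2L,
                      max_epochs = 6L, seed = 10)
  m <- build_model(micro_spec(), seed = 11)
  f1 <- train_fold(m, data, data, cfg)
  f2 <- train_fold(m, data, data, cfg)
  expect_identical(f1$history, f2$history)
  # learning-rate sequence is a product of halvings only
  expect_true(all(f1$history$lr %in% (cfg$learning_rate / 2^(0:10))))
  # checkpointed model reproduces the minimum validation loss
  sc <- forward(f1$model, data$clips)
  y <- gaitscreen:::labels_to_onehot(data$labels)
  expect_equal(gaitscreen:::bce_loss(sc, y), min(f1$history$val_loss))
})

test_that("degenerate training inputs are rejected", {
  data <- four_clip_set()
  m <- build_model(micro_spec(), seed = 1)
  empty <- list(clips = list(), labels = character(0))
  expect_error(train_fold(m, empty, data, train_config()),
               class = "gaitscreen_empty")
  a <- c(data, list(patient = c("p1", "p1", "p2", "p2")))
  b <- c(data, list(patient = c("p2", "p2", "p3", "p3")))
  expect_error(train_fold(m, a, b, train_config()),
               class = "gaitscreen_leak")
})
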