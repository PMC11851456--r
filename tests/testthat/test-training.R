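# Loss formulas, the reduce-on-plateau schedule, early stopping, fit
# determinism and checkpointing.

ns <- asNamespace("cxrseg")

test_that("loss values match closed forms and hand arithmetic", {
  t <- array(c(1, 0, 1, 0), c(2, 2))
  # perfect fit: both terms essentially zero
  p_perfect <- array(c(1, 0, 1, 0), c(2, 2))
  expect_lt(seg_loss(p_perfect, t, "bce"), 1e-5)
  expect_lt(seg_loss(p_perfect, t, "bce+dice") - seg_loss(p_perfect, t, "bce"),
            0.2)  # smooth-Dice term bounded by the smoothing constant
  # probabilities all 0.5: bce = ln 2 per pixel
  expect_equal(seg_loss(array(0.5, c(2, 2)), t, "bce"), log(2), tolerance = 1e-12)
  # hand-computed 2x2 case
  p <- array(c(0.9, 0.2, 0.6, 0.4), c(2, 2))
  bce_hand <- -mean(c(log(0.9), log(1 - 0.2), log(0.6), log(1 - 0.4)))
  expect_equal(seg_loss(p, t, "bce"), bce_hand, tolerance = 1e-12)
  dice_hand <- 1 - (2 * (0.9 + 0.6) + 1) / (sum(p) + 2 + 1)
  expect_equal(seg_loss(p, t, "bce+dice"), bce_hand + dice_hand,
               tolerance = 1e-12)
  # extreme probabilities with opposite labels stay finite
  expect_true(is.finite(seg_loss(array(0, c(2, 2)), array(1, c(2, 2)), "bce")))
})

test_that("the plateau schedule quarters the rate after five stagnant epochs", {
  cfg <- train_config()
  st <- new_train_state(cfg)
  st <- lr_step(st, 0.50, cfg)           # first value: improvement
  expect_equal(st$current_lr, 0.001)
  for (i in 1:5) st <- lr_step(st, 0.50, cfg)  # five stagnant epochs
  expect_equal(st$current_lr, 0.00025)
  expect_true(st$reduced)
  expect_equal(st$epochs_since_improvement, 0)
  # improvement resets the counter without touching the rate
  st <- lr_step(st, 0.60, cfg)
  expect_equal(st$current_lr, 0.00025)
  expect_equal(st$epochs_since_improvement, 0)
  # two consecutive plateaus compose multiplicatively
  for (i in 1:10) st <- lr_step(st, 0.60, cfg)
  expect_equal(st$current_lr, 0.001 * 0.25^3, tolerance = 1e-12)
  # the val_loss monitor is minimized instead
  cfg2 <- train_config(monitor = "val_loss")
  st2 <- new_train_state(cfg2)
  st2 <- lr_step(st2, 1.0, cfg2)
  st2 <- lr_step(st2, 0.5, cfg2)
  expect_equal(st2$epochs_since_improvement, 0)
  st2 <- lr_step(st2, 0.9, cfg2)
  expect_equal(st2$epochs_since_improvement, 1)
})

test_that("invalid training configurations are rejected", {
  expect_error(train_config(lr_factor = 1.5), class = "cxrseg_config_error")
  expect_error(train_config(plateau_patience = 0), class = "cxrseg_config_error")
  expect_error(train_config(loss_name = "mse"), class = "cxrseg_config_error")
  expect_error(train_config(monitor = "train_acc"), class = "cxrseg_config_error")
})

test_that("zero-epoch fits return initialized weights and empty history", {
  pairs <- phantom_pairs(2, size = 16, seed = 2)
  mc <- tiny_model_config(size = 16, C = 2)
  fit <- cxrseg_fit(list(train = pairs), model = mc,
                    config = train_config(max_epochs = 0, seed = 1))
  expect_equal(nrow(fit$state$history), 0)
  ref <- cxrseg_model(mc, seed = 1)
  expect_identical(fit$model$params, ref$params)
  expect_error(cxrseg_fit(list(train = list()), model = mc,
                          config = train_config(max_epochs = 1)),
               class = "cxrseg_validation_error")
})

test_that("fits are deterministic under a fixed seed", {
  pairs <- phantom_pairs(3, size = 16, seed = 4)
  mc <- tiny_model_config(size = 16, C = 2, variant = "MBL")
  tc <- train_config(max_epochs = 3, batch_size = 2, seed = 11)
  f1 <- cxrseg_fit(list(train = pairs[1:2], val = pairs[3]), model = mc, config = tc)
  f2 <- cxrseg_fit(list(train = pairs[1:2], val = pairs[3]), model = mc, config = tc)
  expect_identical(f1$state$history, f2$state$history)
  expect_identical(f1$model$params, f2$model$params)
  # learning rate never increases along a run
  expect_true(all(diff(f1$state$history$lr) <= 0))
})

test_that("early stopping restores the best-monitor checkpoint", {
  pairs <- phantom_pairs(2, size = 16, seed = 6)
  mc <- tiny_model_config(size = 16, C = 2, variant = "BL")
  tc <- train_config(max_epochs = 12, batch_size = 2, seed = 3,
                     early_stop_patience = 2, plateau_patience = 1)
  fit <- cxrseg_fit(list(train = pairs), model = mc, config = tc)
  h <- fit$state$history
  if (fit$stopped == "early_stop") {
    best_epoch <- which.max(h$val_jaccard)
    expect_gte(nrow(h), best_epoch + 2)
  }
  expect_equal(fit$state$best_monitor_value, max(h$val_jaccard))
  # restored weights reproduce the recorded best monitor value
  ev <- ns$evaluate_pairs(fit$model, pairs, tc$loss_name,
                          fit$model$config$binarize_threshold)
  expect_equal(ev$jaccard, fit$state$best_monitor_value, tolerance = 1e-12)
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  mc <- tiny_model_config(size = 16, C = 2)
  m <- cxrseg_model(mc, seed = 9)
  f <- tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  expect_true(file.exists(paste0(f, ".yml")))
  m2 <- load_checkpoint(f, mc)
  expect_identical(m2$params, m$params)
  img <- rand_fm(16, 16, 3, seed = 1)
  expect_identical(predict(m, img)$probabilities,
                   predict(m2, img)$probabilities)
  other <- tiny_model_config(size = 16, C = 4)
  expect_error(load_checkpoint(f, other), class = "cxrseg_config_error")
})
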