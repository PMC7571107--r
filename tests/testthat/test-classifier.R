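test_that("the architecture reproduces the printed layer inventory", {
  model <- build_model(cnn_config())
  counts <- table(model$architecture$type)
  expect_equal(unname(counts[["conv"]]), 8L)
  expect_equal(unname(counts[["pool"]]), 4L)
  expect_equal(unname(counts[["dropout"]]), 2L)
  expect_equal(unname(counts[["dense"]]), 3L)
  # spatial size evolves 28 -> 14 -> 7 -> 3 -> 1 under floor-division pooling
  expect_equal(model$final_shape, c(1L, 1L, 256L))
})

test_that("invalid configurations are rejected", {
  expect_error(cnn_config(conv_channels = c(32, 64, 128)), "8 convolution")
  expect_error(cnn_config(fc_depths = c(256, 2)), "ending in 1")
  expect_error(cnn_config(dropout_rate = 1), "dropout_rate")
  expect_error(build_model(cnn_config(input_size = 8L)), "too small")
})

test_that("parameter count matches closed-form arithmetic and is build-stable", {
  cfg <- cnn_config()
  model <- build_model(cfg)
  ch <- c(1L, cfg$conv_channels)
  conv_params <- sum(ch[-9] * ch[-1] * 9L + ch[-1])
  fc_in <- c(256L, cfg$fc_depths[-3])
  fc_params <- sum(fc_in * cfg$fc_depths + cfg$fc_depths)
  expect_equal(n_parameters(model), conv_params + fc_params)
  expect_equal(n_parameters(build_model(cfg)), n_parameters(model))
  # identical seeds give identical weights; different seeds do not
  expect_identical(build_model(cfg)$weights, model$weights)
  expect_false(identical(build_model(cnn_config(seed = 2))$weights,
                         model$weights))
})

test_that("zero training epochs leave the model untouched", {
  toy <- separable_toy_set(10)
  model <- build_model(toy_config())
  out <- train_cnn(model, toy, epochs = 0L)
  expect_identical(out$weights, model$weights)
  expect_equal(nrow(out$history), 0L)
})

test_that("training contracts: label count, class balance, image shape", {
  toy <- separable_toy_set(10)
  model <- build_model(toy_config())
  expect_error(train_cnn(model, toy, y = rep("stressed", 3)), "match")
  expect_error(train_cnn(model, toy, y = rep("stressed", 20)), "single class")
  small <- array(0, dim = c(14, 14, 4))
  expect_error(train_cnn(model, small, y = c(0, 1, 0, 1)), "28x28")
  expect_error(predict(model, small), "28x28")
})

test_that("a separable toy set is fit to training accuracy 1 with a clean loss trend", {
  toy <- separable_toy_set(60, seed = 42)
  model <- build_model(toy_config(epochs = 10, seed = 3))
  model <- suppressWarnings(train_cnn(model, toy))
  expect_equal(model$history$train_acc[10], 1.0)
  # loss trends firmly downward; single-epoch noise tolerated
  loss <- model$history$train_loss
  expect_lt(loss[10], loss[1])
  expect_lt(cor(seq_along(loss), loss, method = "spearman"), -0.7)
  # depth-1 oracle: the classes are separable by mean occupied row
  mean_row <- apply(toy$pixels, 3L, function(m) mean(apply(m, 2L, which.max)))
  oracle_acc <- mean((mean_row < 14.5) == (toy$info$condition == "stressed"))
  expect_equal(oracle_acc, 1.0)
  # and the trained network reproduces the separation on its inputs
  pred <- predict(model, toy, type = "label")
  expect_equal(mean(pred == toy$info$condition), 1.0)
})

test_that("training is bit-reproducible under a fixed seed", {
  toy <- separable_toy_set(20, seed = 7)
  run <- function() {
    m <- build_model(toy_config(epochs = 3, seed = 11))
    suppressWarnings(train_cnn(m, toy))
  }
  m1 <- run()
  m2 <- run()
  expect_identical(m1$history, m2$history)
  expect_identical(m1$weights, m2$weights)
})

test_that("prediction is deterministic, order-invariant, and ties go to stressed", {
  toy <- separable_toy_set(15, seed = 5)
  model <- build_model(toy_config(seed = 2))
  p <- predict(model, toy)
  expect_true(all(p >= 0 & p <= 1))
  # repeat of the same call is bit-identical
  expect_identical(predict(model, toy), p)
  # batch-order invariance up to float accumulation (BLAS edge tiles)
  perm <- rev(seq_len(n_images(toy)))
  expect_equal(predict(model, toy[perm]), p[perm], tolerance = 1e-6)
  dup <- toy[c(1, 1, 2)]
  pd <- predict(model, dup)
  expect_identical(pd[1], pd[2])
  # an all-zero network outputs exactly 0.5, labeled stressed by the tie rule
  zero <- model
  zero$weights <- lapply(zero$weights, function(w) { w[] <- 0; w })
  zp <- predict(zero, toy, type = "both")
  expect_equal(unique(zp$prob), 0.5)
  expect_equal(unique(zp$label), "stressed")
})

test_that("frequency-domain image sets are rescaled consistently at train and predict", {
  imgs <- separable_toy_set(30, seed = 9)
  fr <- to_frequency_images(imgs)
  model <- build_model(toy_config(epochs = 4, seed = 13))
  model <- suppressWarnings(train_cnn(model, fr))
  expect_equal(model$rescale, 255)
  # automatic rescale at prediction equals the explicit 0-1 rescale used in
  # training, so train and predict see identical inputs
  expect_equal(model$center, 0.5)
  p_auto <- predict(model, fr)
  p_manual <- predict(model, fr$pixels, rescale = 255, center = 0.5)
  expect_identical(p_auto, p_manual)
  expect_false(identical(p_auto, predict(model, fr$pixels, rescale = 1, center = 0)))
})
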