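test_that("architectures match their declared layer plans by introspection", {
  zoo <- model_zoo()
  for (i in seq_len(nrow(zoo))) {
    m <- build_model(zoo$name[i], input_length = 60, n_classes = 4, seed = 1)
    expect_equal(count_conv_layers(m), zoo$conv[i], label = zoo$name[i])
    expect_equal(count_layers(m), zoo$layers[i], label = zoo$name[i])
  }
  # specific structural traits
  mc <- build_model("MCDCNN", 60, 4)
  types <- vapply(mc$stages, `[[`, character(1), "type")
  expect_equal(sum(types == "pool"), 2)
  expect_true(all(vapply(mc$stages[types == "pool"], `[[`, character(1),
                         "kind") == "max"))
  expect_equal(sum(types == "dense"), 2) # FC feature layer + output
  rn <- build_model("ResNet", 60, 4)
  expect_equal(sum(vapply(rn$stages, `[[`, character(1), "type") ==
                     "resblock"), 3)
  expect_error(build_model("transformer", 60, 4), "unknown model")
})

test_that("untrained models emit valid probability rows", {
  set.seed(61)
  X <- matrix(rnorm(7 * 60), 7)
  for (nm in model_zoo()$name) {
    p <- predict_model(build_model(nm, 60, 3, seed = 2), X)$proba
    expect_equal(rowSums(p), rep(1, 7), tolerance = 1e-6)
    expect_true(all(p >= 0))
  }
})

test_that("prediction is deterministic, argmax-consistent and batch independent", {
  set.seed(62)
  m <- build_model("CNN", 40, 3, seed = 3)
  X <- matrix(rnorm(9 * 40), 9)
  X[5, ] <- X[2, ] # duplicated row
  p1 <- predict_model(m, X)
  expect_equal(p1$proba[5, ], p1$proba[2, ])
  expect_identical(p1$labels[5], p1$labels[2])
  expect_equal(p1$labels, apply(p1$proba, 1, which.max))
  # one-by-one equals batched
  p_single <- t(vapply(seq_len(9), function(i) {
    predict_model(m, X[i, , drop = FALSE])$proba[1, ]
  }, numeric(3)))
  expect_equal(p_single, p1$proba, tolerance = 1e-5)
  expect_error(predict_model(m, matrix(0, 2, 39)), "length")
})

test_that("training configs default to the per-architecture protocol", {
  cfg <- train_config("MCDCNN")
  expect_equal(cfg$optimizer, "sgd")
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 500L)
  expect_true(is.na(cfg$lr_decay))
  cfg2 <- train_config("CNN")
  expect_equal(cfg2$optimizer, "adam")
  expect_equal(cfg2$batch_size, 16L)
  expect_equal(cfg2$learning_rate, 1e-4)
  cfg3 <- train_config("MLP")
  expect_equal(cfg3$optimizer, "adadelta")
  expect_equal(cfg3$lr_decay, 0.5)
  cfg4 <- train_config("FCN", batch_size = 8, learning_rate = 0.01)
  expect_equal(cfg4$batch_size, 8L)
  expect_equal(cfg4$learning_rate, 0.01)
})

test_that("early stopping halts after the patience window and keeps best weights", {
  set.seed(63)
  # random labels on a held-out set: validation loss cannot keep improving
  X <- matrix(rnorm(40 * 30), 40)
  y <- sample(c("a", "b"), 40, TRUE)
  Xv <- matrix(rnorm(16 * 30), 16)
  yv <- sample(c("a", "b"), 16, TRUE)
  m <- build_model("MCDCNN", 30, 2, seed = 4)
  cfg <- train_config("MCDCNN", epochs = 50, early_stopping_patience = 0,
                      seed = 5)
  fit <- train_model(m, list(X = X, y = y), list(X = Xv, y = yv), cfg)
  # patience 0: stops at the first non-improving epoch, well before 50
  expect_lt(nrow(fit$history), 50)
})

test_that("a separable two-class task trains to high validation accuracy", {
  specs <- separated_specs()[c("A", "E")] # disjoint amplitude bands
  tg <- time_grid(30, 9)
  rec <- generate_labeled_dataset(c(A = 60L, E = 60L), specs, tg,
                                  noise_sd = 10, seed = 64)
  ds <- cut_to_length(rec, 30, 9)
  idx <- stratified_kfold_split(ds$y, 5, seed = 65)$folds[[1]]
  std <- standardize_signals(ds$X[idx$train, ], ds$X[idx$test, ])
  m <- build_model("MCDCNN", ncol(ds$X), 2, seed = 6)
  cfg <- train_config("MCDCNN", epochs = 40, early_stopping_patience = 10,
                      seed = 7)
  fit <- train_model(m, list(X = std$train, y = ds$y[idx$train]),
                     list(X = std$others[[1]], y = ds$y[idx$test]), cfg)
  pred <- predict_model(fit, std$others[[1]])
  expect_gte(mean(pred$labels == ds$y[idx$test]), 0.95)
})

test_that("training aborts on NaN loss with a diagnostic", {
  set.seed(66)
  X <- matrix(rnorm(20 * 30, sd = 50), 20)
  m <- build_model("MCDCNN", 30, 2, seed = 8)
  cfg <- train_config("MCDCNN", epochs = 30, learning_rate = 1e300, seed = 9)
  expect_error(
    train_model(m, list(X = X, y = rep(c("a", "b"), 10)),
                list(X = X[1:4, ], y = rep(c("a", "b"), 2)), cfg),
    "loss")
})
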