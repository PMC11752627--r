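test_that("100 items split 64/16/20, disjoint, exhaustive, seed-stable", {
  items <- sprintf("item%03d", 1:100)
  sp <- split_spec(seed = 7)
  out <- split_dataset(items, sp)
  expect_equal(lengths(out), c(train = 64L, validation = 16L, test = 20L))
  expect_partition(out, items)

  out2 <- split_dataset(items, split_spec(seed = 7))
  expect_identical(out, out2)
  out3 <- split_dataset(items, split_spec(seed = 8))
  expect_false(identical(attr(out, "indices"), attr(out3, "indices")))

  expect_error(split_dataset(character(0), sp), "empty")
  expect_error(split_spec(c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("stratified splits keep every class in every subset", {
  labels <- rep(c("A", "N", "O", "~"), times = c(20, 40, 30, 10))
  items <- seq_along(labels)
  out <- split_dataset(items, split_spec(seed = 3), labels = labels)
  expect_equal(lengths(out), c(train = 64L, validation = 16L, test = 20L))
  expect_partition(out, items)
  for (subset in out) {
    expect_setequal(unique(labels[subset]), c("A", "N", "O", "~"))
  }
})

test_that("models output probability rows with argmax, first-index ties", {
  model <- build_model("small", n_classes = 4, input_size = 16, seed = 1)
  set.seed(5)
  imgs <- array(runif(16 * 16 * 3 * 6), c(16, 16, 3, 6))
  model$class_names <- c("A", "N", "O", "~")
  pred <- predict(model, imgs)
  expect_equal(rowSums(pred$scores), rep(1, 6), tolerance = 1e-6)
  expect_true(all(pred$scores >= 0))
  expect_equal(pred$decisions,
               model$class_names[apply(pred$scores, 1, which.max)])

  # uniform scores tie-break to the first class
  expect_equal(max.col(matrix(0.25, 1, 4), ties.method = "first"), 1L)
  expect_error(build_model("small", n_classes = 1), "at least 2")
  expect_error(predict(model, array(0, c(8, 8, 3, 1))), "does not match")
})

test_that("a pretrained backbone trains only the replaced head", {
  backbone <- list(
    name = "fixed-projection",
    n_features = 32,
    features = local({
      proj <- afwave:::with_seed(11, matrix(rnorm(16 * 16 * 3 * 32), ncol = 32))
      function(images) {
        n <- dim(images)[4]
        flat <- t(matrix(images, ncol = n))
        flat %*% proj
      }
    })
  )
  model3 <- build_model(backbone, n_classes = 3, input_size = 16, seed = 2)
  expect_equal(n_trainable_params(model3), 32 * 3 + 3)
  model <- build_model(backbone, n_classes = 2, input_size = 16, seed = 2)
  expect_equal(n_trainable_params(model), 32 * 2 + 2)

  # the head alone learns a separable problem through the frozen features
  data <- make_band_images(30, size = 16, seed = 21)
  sets <- split_dataset(seq_len(60), split_spec(seed = 2), labels = data$labels)
  mk <- function(idx) list(images = data$images[, , , idx, drop = FALSE],
                           labels = data$labels[idx])
  fit <- train(model, mk(sets$train), mk(sets$validation),
               train_config(learning_rate = 1e-2, batch_size = 16,
                            max_epochs = 30, patience = 10, seed = 3))
  pred <- predict(fit$model, data$images[, , , sets$test, drop = FALSE])
  expect_gte(mean(pred$decisions == data$labels[sets$test]), 0.9)
})

test_that("training stops after exactly `patience` flat validation checks", {
  data <- make_band_images(10, size = 12, seed = 4)
  sets <- list(images = data$images, labels = data$labels)
  # zero learning rate: weights frozen, validation accuracy constant
  cfg <- train_config(learning_rate = 0, batch_size = 10, max_epochs = 50,
                      patience = 3, seed = 5)
  model <- build_model("small", n_classes = 2, input_size = 12, seed = 6)
  fit <- train(model, sets, sets, cfg)
  expect_equal(attr(fit$history, "stop_reason"), "early_stop")
  expect_equal(nrow(fit$history), 1 + 3)       # first check + patience lags

  # patience exceeding the epoch budget: runs out of epochs instead
  cfg2 <- train_config(learning_rate = 0, batch_size = 10, max_epochs = 4,
                       patience = 10, seed = 5)
  fit2 <- train(model, sets, sets, cfg2)
  expect_equal(attr(fit2$history, "stop_reason"), "max_epochs")
  expect_equal(nrow(fit2$history), 4)
})

test_that("returned weights come from the best validation check", {
  data <- make_band_images(25, size = 12, seed = 8)
  sets <- split_dataset(seq_len(50), split_spec(seed = 9), labels = data$labels)
  mk <- function(idx) list(images = data$images[, , , idx, drop = FALSE],
                           labels = data$labels[idx])
  model <- build_model("small", n_classes = 2, input_size = 12, seed = 10)
  fit <- train(model, mk(sets$train), mk(sets$validation),
               train_config(learning_rate = 1e-3, batch_size = 16,
                            max_epochs = 12, patience = 4, seed = 11))
  best <- attr(fit$history, "best_val_accuracy")
  expect_equal(best, max(fit$history$val_accuracy))
  pred <- predict(fit$model, mk(sets$validation)$images)
  expect_equal(mean(pred$decisions == data$labels[sets$validation]), best)
})

test_that("the small CNN learns a linearly separable two-class image task", {
  data <- make_band_images(200, size = 12, seed = 12)
  accs <- sapply(c(31, 32, 33), function(seed) {
    sets <- split_dataset(seq_len(400), split_spec(seed = seed),
                          labels = data$labels)
    mk <- function(idx) list(images = data$images[, , , idx, drop = FALSE],
                             labels = data$labels[idx])
    model <- build_model("small", n_classes = 2, input_size = 12, seed = seed)
    fit <- train(model, mk(sets$train), mk(sets$validation),
                 train_config(learning_rate = 1e-3, batch_size = 64,
                              max_epochs = 20, patience = 5, seed = seed))
    pred <- predict(fit$model, mk(sets$test)$images)
    mean(pred$decisions == data$labels[sets$test])
  })
  expect_gte(stats::median(accs), 0.9)

  expect_error(
    train(build_model("small", n_classes = 2, input_size = 12),
          list(images = data$images[, , , 1:4, drop = FALSE],
               labels = rep("hi", 4)),
          list(images = data$images[, , , 1:2, drop = FALSE],
               labels = c("hi", "lo"))),
    "single class")
  expect_warning(
    train(build_model("small", n_classes = 3, input_size = 12,
                      class_names = c("hi", "lo", "zz")),
          list(images = data$images[, , , c(1, 250), drop = FALSE],
               labels = c("hi", "lo")),
          list(images = data$images[, , , c(2, 251), drop = FALSE],
               labels = c("hi", "lo")),
          train_config(learning_rate = 0, batch_size = 2, max_epochs = 1,
                       patience = 1)),
    "absent")
})
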