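test_that("training on a separable toy set reaches perfect accuracy", {
  spikes <- toy_separable_set(n_per = 30L)
  fit <- train_cnn(spikes, config = training_config(epochs = 50, seed = 1))
  h <- fit$history
  expect_equal(nrow(h), 50L)
  expect_equal(h$train_accuracy[50], 1)
  # monotone capacity sanity: the final loss does not exceed the first
  expect_lte(h$train_loss[50], h$train_loss[1])
  # prediction recovers the training labels
  expect_equal(predict(fit, spikes), spikes$label)
})

test_that("deterministic training is exactly reproducible", {
  spikes <- toy_separable_set(n_per = 10L)
  cfg <- training_config(epochs = 3, seed = 9, deterministic = TRUE)
  a <- train_cnn(spikes, config = cfg)
  b <- train_cnn(spikes, config = cfg)
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("probability rows are normalized and permutation-equivariant", {
  spikes <- toy_separable_set(n_per = 10L)
  fit <- train_cnn(spikes, config = training_config(epochs = 3, seed = 2))
  p <- as.matrix(predict(fit, spikes, type = "prob"))
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-6)
  perm <- sample(nrow(spikes))
  p2 <- as.matrix(predict(fit, spikes[perm, ], type = "prob"))
  expect_equal(p2, p[perm, ], tolerance = 1e-12)
  # a duplicated waveform gives identical rows
  five <- spikes[rep(1, 5), ]
  p5 <- as.matrix(predict(fit, five, type = "prob"))
  expect_true(all(apply(p5, 2, function(col) max(col) - min(col)) == 0))
})

test_that("training validates inputs", {
  spikes <- toy_separable_set(n_per = 5L)
  missing2 <- dplyr::filter(spikes, label != 2L)
  expect_error(train_cnn(missing2), "class 2")
  spec <- build_model_spec(32, 3)
  expect_error(train_cnn(spikes, spec = spec), "expects 32")
  fit <- train_cnn(spikes, config = training_config(epochs = 1, seed = 1))
  short <- waveform_tbl(matrix(rnorm(2 * 16), 2, 16), c(1L, 2L))
  expect_error(predict(fit, short), "expects 64")
})

test_that("the monitor set produces a complete held-out loss history", {
  spikes <- small_sim_set(duration_s = 2, seed = 13)
  sp <- split_dataset(spikes, 0.5, seed = 13)
  fit <- train_cnn(sp$train, config = training_config(epochs = 4, seed = 13),
                   monitor = sp$test)
  h <- fit$history
  expect_equal(nrow(h), 4L)
  expect_true(all(is.finite(h$monitor_loss)))
  expect_true(all(h$monitor_accuracy >= 0 & h$monitor_accuracy <= 1))
})

test_that("saved models predict bit-identically after loading", {
  spikes <- toy_separable_set(n_per = 8L)
  fit <- train_cnn(spikes, config = training_config(epochs = 2, seed = 4))
  dir <- withr::local_tempdir()
  save_spike_cnn(fit, dir)
  back <- load_spike_cnn(dir)
  expect_identical(as.matrix(predict(fit, spikes, type = "prob")),
                   as.matrix(predict(back, spikes, type = "prob")))
  expect_error(load_spike_cnn(withr::local_tempdir()), "model directory")
})

test_that("a global affine amplitude change barely moves held-out accuracy", {
  spikes <- small_sim_set(duration_s = 2.5, seed = 17)
  sp <- split_dataset(spikes, 0.5, seed = 17)
  cfg <- training_config(epochs = 8, seed = 17)
  base_fit <- train_cnn(sp$train, config = cfg)
  base_acc <- mean(predict(base_fit, sp$test) == sp$test$label)

  affine <- function(w, a, b) {
    m <- waveform_matrix(w) * a + b
    waveform_tbl(m, waveform_labels(w))
  }
  shift_fit <- train_cnn(affine(sp$train, 37.5, -11), config = cfg)
  shift_acc <- mean(predict(shift_fit, affine(sp$test, 37.5, -11)) ==
                      sp$test$label)
  expect_lt(abs(shift_acc - base_acc), 0.01)
})

test_that("tidy and glance expose the history and the fit summary", {
  spikes <- toy_separable_set(n_per = 6L)
  fit <- train_cnn(spikes, config = training_config(epochs = 2, seed = 5))
  expect_identical(tidy(fit), fit$history)
  g <- glance(fit)
  expect_equal(g$n_parameters, 209231L)
  expect_equal(g$epochs, 2L)
  expect_equal(g$n_train, nrow(spikes))
})
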