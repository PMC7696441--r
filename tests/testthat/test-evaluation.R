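test_that("stratified splits hit the exact requested sizes", {
  w <- waveform_tbl(matrix(rnorm(100 * 4), 100, 4), rep(1:2, each = 50))
  sp <- split_dataset(w, 0.2, seed = 1)
  expect_equal(nrow(sp$train), 20L)
  expect_equal(nrow(sp$test), 80L)
  expect_equal(as.integer(table(waveform_labels(sp$train))), c(10L, 10L))
  # disjoint and exhaustive
  key <- function(d) apply(waveform_matrix(d), 1, paste, collapse = ",")
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_equal(nrow(sp$train) + nrow(sp$test), 100L)
  # deterministic
  sp2 <- split_dataset(w, 0.2, seed = 1)
  expect_identical(sp, sp2)
})

test_that("a 5% split of 3400 spikes yields 170 training spikes", {
  w <- waveform_tbl(matrix(rnorm(3400 * 4), 3400, 4),
                    sample(rep(1:3, length.out = 3400)))
  sp <- split_dataset(w, 0.05, seed = 2)
  expect_equal(nrow(sp$train), 170L)
})

test_that("chronological splits take the earliest spikes of each class", {
  m <- matrix(seq_len(20 * 4), 20, 4)
  w <- waveform_tbl(m, rep(1:2, 10))
  sp <- split_dataset(w, 0.5, strategy = "chronological")
  # first 5 occurrences of each class = rows 1..10
  expect_equal(waveform_matrix(sp$train), m[1:10, ])
})

test_that("sparse classes are rejected with the class named", {
  w <- waveform_tbl(matrix(rnorm(5 * 4), 5, 4), c(1L, 1L, 1L, 1L, 2L))
  expect_error(split_dataset(w, 0.5), "class 2",
               class = "spikecnn_sparse_class")
})

test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion(c(1L, 1L, 2L), c(1L, 2L, 2L))
  expect_equal(unclass(unname(cm)), matrix(c(1L, 0L, 1L, 1L), 2, 2),
               ignore_attr = TRUE)
  y <- sample.int(4, 50, replace = TRUE)
  expect_equal(unname(diag(confusion(y, y, 4L))), unname(as.vector(table(factor(y, 1:4)))))
  expect_equal(sum(confusion(y, y, 4L)), 50L)
  empty <- confusion(integer(0), integer(0), n_classes = 3L)
  expect_equal(sum(empty), 0L)
  expect_error(confusion(1L, 5L, n_classes = 2L), "exceed")
})

test_that("accuracy equals trace over total and matches brute force", {
  expect_equal(accuracy(confusion(c(1L, 2L), c(1L, 2L))), 1)
  cm <- matrix(c(90L, 30L, 10L, 70L), 2, 2)
  expect_equal(accuracy(structure(cm, class = c("confusion_matrix", "matrix"))),
               0.80)
  set.seed(1)
  y_true <- sample.int(3, 1000, replace = TRUE)
  y_pred <- sample.int(3, 1000, replace = TRUE)
  expect_equal(accuracy(confusion(y_true, y_pred)),
               oracle_accuracy(y_true, y_pred))
  expect_error(accuracy(confusion(integer(0), integer(0), 2L)), "empty")
})

test_that("macro F matches the hand-worked example and handles silent classes", {
  cm <- structure(matrix(c(90L, 30L, 10L, 70L), 2, 2),
                  class = c("confusion_matrix", "matrix"))
  # per class: P1 = 90/120, R1 = 90/100 -> F1 = 0.818182
  #            P2 = 70/80,  R2 = 70/100 -> F2 = 0.777778
  expect_equal(macro_f(cm), (0.8181818181818182 + 0.7777777777777778) / 2,
               tolerance = 1e-12)
  expect_equal(macro_f(cm), oracle_macro_f(cm), tolerance = 1e-15)
  # never-predicted class contributes zero, dragging macro F below accuracy
  cm0 <- structure(matrix(c(95L, 5L, 0L, 0L), 2, 2),
                   class = c("confusion_matrix", "matrix"))
  expect_equal(macro_f(cm0), oracle_macro_f(cm0))
  expect_lt(macro_f(cm0), accuracy(cm0))
  expect_error(macro_f(structure(matrix(1L), class = "confusion_matrix")),
               "2 classes")
})

test_that("macro F equals accuracy for balanced symmetric errors, not otherwise", {
  sym <- structure(matrix(c(80L, 20L, 20L, 80L), 2, 2),
                   class = c("confusion_matrix", "matrix"))
  expect_equal(macro_f(sym), accuracy(sym), tolerance = 1e-12)
  # errors concentrated in a rare class: accuracy stays high, macro F drops
  rare <- structure(matrix(c(950L, 40L, 0L, 10L), 2, 2),
                    class = c("confusion_matrix", "matrix"))
  expect_gt(accuracy(rare), 0.9)
  expect_lt(macro_f(rare), accuracy(rare) - 0.2)
})

test_that("metrics agree with brute-force oracles on random matrices", {
  set.seed(42)
  for (rep in 1:100) {
    k <- sample(2:6, 1)
    cm <- random_confusion(k)
    cmo <- structure(cm, class = c("confusion_matrix", "matrix"))
    y_pairs <- which(cm > 0, arr.ind = TRUE)
    expect_equal(macro_f(cmo), oracle_macro_f(cm), tolerance = 1e-12)
    expect_equal(accuracy(cmo), sum(diag(cm)) / sum(cm), tolerance = 1e-12)
  }
})

test_that("cross-entropy matches closed forms and a brute-force sum", {
  onehot <- diag(3)[c(1, 2, 3), ]
  expect_equal(cross_entropy(onehot, c(1L, 2L, 3L)), 0, tolerance = 1e-10)
  unif <- matrix(1 / 3, 5, 3)
  expect_equal(cross_entropy(unif, rep(2L, 5)), log(3), tolerance = 1e-12)
  set.seed(7)
  for (rep in 1:100) {
    p <- matrix(rexp(8 * 4), 8, 4)
    p <- p / rowSums(p)
    y <- sample.int(4, 8, replace = TRUE)
    expect_equal(cross_entropy(p, y), oracle_cross_entropy(p, y),
                 tolerance = 1e-12)
  }
  expect_error(cross_entropy(unif, rep(2L, 3)), "rows")
})

test_that("per-class metrics carry precision, recall, F1 and support", {
  cm <- structure(matrix(c(90L, 30L, 10L, 70L), 2, 2),
                  class = c("confusion_matrix", "matrix"))
  pc <- per_class_metrics(cm)
  expect_equal(pc$precision, c(90 / 120, 70 / 80))
  expect_equal(pc$recall, c(0.9, 0.7))
  expect_equal(pc$support, c(100, 100), ignore_attr = TRUE)
  expect_equal(sum(pc$support), sum(cm))
})
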