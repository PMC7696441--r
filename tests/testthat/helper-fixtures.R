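# shared fixtures, all generated in code

# tiny, perfectly separable labeled set: three noise-free distinct templates,
# n_per copies each with mild amplitude scaling
toy_separable_set <- function(n_per = 30L, n_samples = 64L, seed = 42L) {
  bank <- make_templates(3L, n_samples, "easy", seed = seed)
  set.seed(seed)
  idx <- rep(1:3, each = n_per)
  amps <- runif(length(idx), 0.9, 1.1)
  m <- bank$templates[idx, ] * amps
  waveform_tbl(m, idx)
}

# small simulated labeled set (fast to generate)
small_sim_set <- function(duration_s = 3, noise_level = 0.15, seed = 7L,
                          difficulty = "easy") {
  generate_labeled_set(
    simulation_config(duration_s = duration_s, noise_level = noise_level,
                      seed = seed),
    difficulty)
}

# tiny architecture for gradient checks: cheap but structurally complete
tiny_spec <- function(input_length = 8L, n_classes = 2L, dropout = 0,
                      batch_norm = "first") {
  build_model_spec(input_length, n_classes,
                   conv_filters = c(2L, 3L, 3L, 2L),
                   dense_units = c(7L, 5L),
                   dropout_rate = dropout, batch_norm = batch_norm)
}

# brute-force metric oracles, element-by-element loops kept deliberately
# independent of the package implementations
oracle_accuracy <- function(y_true, y_pred) {
  hits <- 0L
  for (i in seq_along(y_true)) if (y_true[i] == y_pred[i]) hits <- hits + 1L
  hits / length(y_true)
}

oracle_macro_f <- function(cm) {
  n <- nrow(cm)
  fs <- numeric(n)
  for (i in seq_len(n)) {
    tp <- cm[i, i]
    fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (j != i) {
        fp <- fp + cm[j, i]
        fn <- fn + cm[i, j]
      }
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    fs[i] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  s <- 0
  for (i in seq_len(n)) s <- s + fs[i]
  s / n
}

oracle_cross_entropy <- function(probs, y) {
  s <- 0
  for (i in seq_along(y)) {
    p <- probs[i, y[i]]
    if (p < 1e-12) p <- 1e-12
    s <- s - log(p)
  }
  s / length(y)
}

random_confusion <- function(n_classes, max_count = 50L) {
  m <- matrix(sample.int(max_count, n_classes^2, replace = TRUE) - 1L,
              n_classes, n_classes)
  # make sure the matrix is non-degenerate
  diag(m) <- diag(m) + 1L
  m
}
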