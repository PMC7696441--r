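#' Split a labeled spike set into training and testing portions
#'
#' Implements the training-fraction protocol: `n_train = round(fraction *
#' n)` spikes go to the training set, stratified per class with
#' largest-remainder rounding so class proportions are preserved as closely
#' as integer counts allow.
#'
#' @param data Waveform tibble.
#' @param train_fraction Fraction of spikes used for training, in (0, 1).
#' @param strategy `"random_stratified"` shuffles within each class with
#'   the given seed; `"chronological"` takes the earliest rows of each class
#'   (matching the workflow of hand-labeling an initial stretch of a
#'   recording and sorting the rest automatically).
#' @param seed Seed for the stratified shuffle.
#' @return List with waveform tibbles `train` and `test` (disjoint,
#'   exhaustive, original row order within each).
#' @examples
#' spikes <- waveform_tbl(matrix(rnorm(400), 100, 4),
#'                        rep(1:2, each = 50))
#' sp <- split_dataset(spikes, 0.2, seed = 1)
#' nrow(sp$train)
#' @export
split_dataset <- function(data, train_fraction,
                          strategy = c("random_stratified", "chronological"),
                          seed = 1L) {
  strategy <- match.arg(strategy)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("train_fraction must be in (0, 1)")
  }
  y <- waveform_labels(data)
  n <- length(y)
  tab <- table(y)
  small <- names(tab)[tab < 2L]
  if (length(small) > 0L) {
    abort(sprintf("class %s has fewer than 2 spikes; too sparse to split",
                  paste(small, collapse = ", ")),
          class = "spikecnn_sparse_class")
  }
  n_train <- round(train_fraction * n)
  classes <- as.integer(names(tab))
  quota <- train_fraction * as.numeric(tab)
  base <- floor(quota)
  rem <- n_train - sum(base)
  if (rem > 0) {
    # largest fractional remainder; ties broken by class order
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  } else if (rem < 0) {
    cut <- order(quota - base, decreasing = FALSE)
    cut <- cut[base[cut] > 0][seq_len(-rem)]
    base[cut] <- base[cut] - 1
  }
  take <- integer(0)
  for (i in seq_along(classes)) {
    rows <- which(y == classes[i])
    k <- base[i]
    if (k == 0L) next
    sel <- if (strategy == "chronological") rows[seq_len(k)]
           else local_seeded(seed + classes[i], rows[sample.int(length(rows), k)])
    take <- c(take, sel)
  }
  take <- sort(take)
  list(train = data[take, , drop = FALSE],
       test = data[setdiff(seq_len(n), take), , drop = FALSE])
}

#' Confusion matrix of true versus predicted cluster labels
#'
#' Rows are true classes, columns predicted classes, both covering
#' `1..n_classes`.
#'
#' @param y_true,y_pred Integer label vectors of equal length.
#' @param n_classes Number of classes (defaults to the largest label seen).
#' @return An `n x n` integer matrix of class `confusion_matrix`.
#' @examples
#' confusion(c(1, 1, 2), c(1, 2, 2))
#' @export
confusion <- function(y_true, y_pred, n_classes = NULL) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have the same length")
  }
  if (is.null(n_classes)) {
    n_classes <- if (length(y_true) == 0L) 0L else max(y_true, y_pred)
  }
  if (length(y_true) > 0L) {
    check_labels(y_true); check_labels(y_pred)
    if (max(y_true, y_pred) > n_classes) {
      abort(sprintf("labels exceed n_classes = %d", n_classes))
    }
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes),
                               predicted = seq_len(n_classes)))
  for (i in seq_along(y_true)) {
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  }
  structure(cm, class = c("confusion_matrix", "matrix", "array"))
}

#' Overall accuracy from a confusion matrix
#'
#' The fraction of correctly classified spikes: trace over total count.
#'
#' @param cm A [confusion()] matrix.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Macro-averaged F-measure from a confusion matrix
#'
#' For each class `i`, precision `P_i = TP_i / (TP_i + FP_i)` (column-wise)
#' and recall `R_i = TP_i / (TP_i + FN_i)` (row-wise) combine into
#' `F_i = 2 P_i R_i / (P_i + R_i)`; the macro F-measure is the unweighted
#' mean of the `F_i`. A class that is never predicted or never occurs
#' contributes `F_i = 0`, which is what makes the measure sensitive to rare
#' clusters that plain accuracy glosses over.
#'
#' @param cm A [confusion()] matrix with at least 2 classes.
#' @return Macro F-measure in `[0, 1]`.
#' @examples
#' macro_f(confusion(c(1, 1, 2, 2), c(1, 1, 2, 1)))
#' @export
macro_f <- function(cm) {
  n <- nrow(cm)
  if (is.null(n) || n < 2L) abort("macro_f needs at least 2 classes")
  f <- per_class_metrics(cm)$f1
  mean(f)
}

#' Per-class precision, recall, F1 and support
#'
#' @param cm A [confusion()] matrix.
#' @return Tibble with one row per class.
#' @export
per_class_metrics <- function(cm) {
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  p <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  r <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  tibble::tibble(class = seq_len(nrow(cm)), precision = p, recall = r,
                 f1 = f, support = rowSums(cm))
}

#' Mean categorical cross-entropy
#'
#' Mean of `-log p(true class)` over spikes, with probabilities clipped at
#' `1e-12`.
#'
#' @param probs Numeric matrix of predicted probabilities (rows sum to 1).
#' @param y_true Integer class indices (1-based columns of `probs`).
#' @return Non-negative loss value.
#' @export
cross_entropy <- function(probs, y_true) {
  probs <- as.matrix(probs)
  if (nrow(probs) != length(y_true)) {
    abort(sprintf("probs has %d rows but y_true has %d entries",
                  nrow(probs), length(y_true)))
  }
  if (any(y_true < 1L | y_true > ncol(probs))) {
    abort("y_true indices outside the probability columns")
  }
  p <- probs[cbind(seq_along(y_true), y_true)]
  mean(-log(pmax(p, 1e-12)))
}

#' Evaluate a fitted model on a labeled spike set
#'
#' @param model A fitted [train_cnn()] model.
#' @param data Labeled waveform tibble.
#' @return A `spike_metrics` object: accuracy, macro F, confusion matrix,
#'   per-class metrics, and counts.
#' @export
evaluate_model <- function(model, data) {
  y <- waveform_labels(data)
  idx <- match(y, model$classes)
  if (anyNA(idx)) abort("data contains labels the model was not trained on")
  probs <- as.matrix(predict(model, data, type = "prob"))
  pred_idx <- max.col(probs)
  cm <- confusion(idx, pred_idx, n_classes = model$spec$n_classes)
  structure(list(accuracy = accuracy(cm), macro_f = macro_f(cm),
                 confusion = cm, per_class = per_class_metrics(cm),
                 cross_entropy = cross_entropy(probs, idx),
                 n = length(y), classes = model$classes),
            class = "spike_metrics")
}

#' @export
print.spike_metrics <- function(x, ...) {
  cat(sprintf("<spike_metrics> n = %d: accuracy %.4f, macro F %.4f, cross-entropy %.5f\n",
              x$n, x$accuracy, x$macro_f, x$cross_entropy))
  print(unclass(x$confusion))
  invisible(x)
}

#' @export
tidy.spike_metrics <- function(x, ...) x$per_class

#' @export
glance.spike_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_f = x$macro_f,
                 cross_entropy = x$cross_entropy, n = x$n)
}

#' Run the training-fraction experiment sweep
#'
#' The package's evaluation protocol: for each training fraction (by
#' default the six canonical fractions 5%, 10%, 20%, 30%, 40% and 50%,
#' experiments E1-E6), split the data, train a fresh classifier, evaluate
#' on the held-out spikes, and collect accuracy, macro F-measure, the
#' confusion matrix and the loss history.
#'
#' @param data Labeled waveform tibble.
#' @param spec Optional [build_model_spec()]; defaults to the data's shape.
#' @param config A [training_config()]; each experiment derives its own
#'   seed from `seed` + experiment index.
#' @param fractions Training fractions to sweep.
#' @param strategy Split strategy, see [split_dataset()].
#' @param seed Base seed for splitting and training.
#' @param out_dir If non-`NULL`, writes `summary.csv` (one row per
#'   experiment) and `report.json` (full metrics incl. confusion matrices
#'   and loss histories) into this directory.
#' @return Tibble with one row per experiment: `experiment`,
#'   `train_fraction`, `n_train`, `n_test`, `accuracy`, `macro_f`,
#'   `cross_entropy`, plus list-columns `confusion`, `per_class`,
#'   `history`.
#' @export
run_experiments <- function(data, spec = NULL, config = training_config(),
                            fractions = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                            strategy = c("random_stratified", "chronological"),
                            seed = 1L, out_dir = NULL) {
  strategy <- match.arg(strategy)
  y <- waveform_labels(data)
  k <- check_class_coverage(y)
  rows <- vector("list", length(fractions))
  for (i in seq_along(fractions)) {
    f <- fractions[i]
    sp <- split_dataset(data, f, strategy = strategy, seed = seed + i)
    ytr <- waveform_labels(sp$train)
    missing <- setdiff(seq_len(k), unique(ytr))
    if (length(missing) > 0L) {
      abort(sprintf("fraction %.3f leaves class %s without training spikes",
                    f, paste(missing, collapse = ", ")),
            class = "spikecnn_sparse_class")
    }
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    fit <- train_cnn(sp$train, spec = spec, config = cfg, monitor = sp$test)
    m <- evaluate_model(fit, sp$test)
    rows[[i]] <- tibble::tibble(
      experiment = paste0("E", i), train_fraction = f,
      n_train = nrow(sp$train), n_test = nrow(sp$test),
      accuracy = m$accuracy, macro_f = m$macro_f,
      cross_entropy = m$cross_entropy,
      confusion = list(m$confusion), per_class = list(m$per_class),
      history = list(fit$history))
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(dplyr::select(out, !dplyr::where(is.list)),
                     file.path(out_dir, "summary.csv"))
    jsonlite::write_json(
      purrr::map(seq_len(nrow(out)), function(i) {
        list(experiment = out$experiment[i],
             train_fraction = out$train_fraction[i],
             n_train = out$n_train[i], n_test = out$n_test[i],
             accuracy = out$accuracy[i], macro_f = out$macro_f[i],
             cross_entropy = out$cross_entropy[i],
             confusion = unclass(out$confusion[[i]]),
             per_class = out$per_class[[i]],
             history = out$history[[i]],
             seed = seed + i)
      }),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Accuracy/macro-F trend across training fractions
#'
#' @param object The tibble returned by [run_experiments()].
#' @param ... Unused.
#' @export
autoplot_experiments <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("accuracy", "macro_f"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$train_fraction,
                                     y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_continuous(labels = function(v) paste0(100 * v, "%")) +
    ggplot2::labs(x = "training fraction", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
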