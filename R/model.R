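#' Training configuration
#'
#' @param epochs Number of passes over the training set (default 50).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,adam_eps Adam moment decay rates and stabilizer.
#' @param bn_momentum Momentum of the batch-normalization running
#'   statistics.
#' @param seed Integer seed used when `deterministic = TRUE`.
#' @param deterministic If `TRUE`, training seeds the RNG from `seed`, so
#'   initialization, shuffling and dropout (and hence the whole loss
#'   history) are exactly reproducible. If `FALSE`, training draws from the
#'   session RNG stream.
#' @param standardize Z-score all amplitudes with the training-set global
#'   mean and standard deviation; the statistics are stored in the model so
#'   prediction is self-contained.
#' @return A `train_config` list.
#' @export
training_config <- function(epochs = 50L, batch_size = 32L,
                            learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                            adam_eps = 1e-8, bn_momentum = 0.9, seed = 1L,
                            deterministic = TRUE, standardize = TRUE) {
  if (epochs < 1L) abort("epochs must be at least 1")
  if (batch_size < 1L) abort("batch_size must be at least 1")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, bn_momentum = bn_momentum,
                 seed = as.integer(seed), deterministic = deterministic,
                 standardize = standardize),
            class = "train_config")
}

#' Train the 1D-CNN spike classifier
#'
#' Fits the convolutional classifier to a labeled waveform tibble with
#' minibatch Adam on the categorical cross-entropy loss. Labels may be any
#' positive integers; they are mapped to consecutive class indices
#' internally and mapped back on prediction, but every class that occurs
#' must have at least one training example.
#'
#' @param data Waveform tibble ([waveform_tbl()] layout) with the training
#'   spikes.
#' @param spec A [build_model_spec()] architecture; by default one is built
#'   for the data's snippet length and number of classes.
#' @param config A [training_config()].
#' @param monitor Optional waveform tibble evaluated (inference mode) after
#'   every epoch; its loss/accuracy land in the history as `monitor_loss`
#'   and `monitor_accuracy`.
#' @return A fitted `spike_cnn` model with the per-epoch `history` tibble.
#' @examples
#' \donttest{
#' spikes <- generate_labeled_set(simulation_config(duration_s = 2))
#' fit <- train_cnn(spikes, config = training_config(epochs = 5))
#' glance(fit)
#' }
#' @export
train_cnn <- function(data, spec = NULL, config = training_config(),
                      monitor = NULL) {
  x <- waveform_matrix(data)
  y_raw <- waveform_labels(data)
  classes <- sort(unique(y_raw))
  k <- check_class_coverage(y_raw)
  if (is.null(spec)) spec <- build_model_spec(ncol(x), k)
  if (spec$input_length != ncol(x)) {
    abort(sprintf("data has %d sample points but the spec expects %d",
                  ncol(x), spec$input_length))
  }
  if (spec$n_classes != k) {
    abort(sprintf("data has %d classes but the spec expects %d",
                  k, spec$n_classes))
  }
  y <- match(y_raw, classes)

  mu <- 0; sdv <- 1
  if (isTRUE(config$standardize)) {
    mu <- mean(x); sdv <- sd(x)
    if (sdv == 0) sdv <- 1
    x <- (x - mu) / sdv
  }
  xm <- NULL; ym <- NULL
  if (!is.null(monitor)) {
    xm <- (waveform_matrix(monitor) - mu) / sdv
    if (ncol(xm) != spec$input_length) {
      abort("monitor set has the wrong number of sample points")
    }
    ym <- match(waveform_labels(monitor), classes)
    if (anyNA(ym)) abort("monitor set contains labels unseen in training")
  }

  compiled <- compile_spec(spec)
  fit_one <- function() {
    params <- init_params(spec, compiled)
    adam_m <- numeric(compiled$n_params)
    adam_v <- numeric(compiled$n_params)
    bn_rmu <- numeric(max(compiled$n_bn, 1L))
    bn_rv <- rep(1, max(compiled$n_bn, 1L))
    adam_t <- 0L
    hist <- vector("list", config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(nrow(x))
      r <- .cnn_epoch(x, y, perm, config$batch_size, compiled$meta,
                      compiled$drop, params, adam_m, adam_v, adam_t,
                      bn_rmu, bn_rv, config$learning_rate, config$beta1,
                      config$beta2, config$adam_eps, config$bn_momentum,
                      spec$n_classes)
      adam_t <- r$adam_t
      row <- tibble::tibble(epoch = ep, train_loss = r$loss,
                            train_accuracy = r$accuracy,
                            monitor_loss = NA_real_,
                            monitor_accuracy = NA_real_)
      if (!is.null(xm)) {
        pm <- .cnn_forward_probs(xm, compiled$meta, compiled$drop, params,
                                 bn_rmu, bn_rv, spec$n_classes)
        row$monitor_loss <- cross_entropy(pm, ym)
        row$monitor_accuracy <- mean(max.col(pm) == ym)
      }
      hist[[ep]] <- row
    }
    list(params = params, bn_rmu = bn_rmu, bn_rv = bn_rv,
         history = dplyr::bind_rows(hist))
  }
  fitted <- if (isTRUE(config$deterministic)) local_seeded(config$seed, fit_one())
            else fit_one()

  structure(list(spec = spec, config = config, classes = classes,
                 params = fitted$params, bn_rmu = fitted$bn_rmu,
                 bn_rv = fitted$bn_rv,
                 standardization = list(mean = mu, sd = sdv),
                 history = fitted$history,
                 n_train = nrow(x)),
            class = "spike_cnn")
}

#' @export
print.spike_cnn <- function(x, ...) {
  h <- x$history
  cat(sprintf("<spike_cnn> %d classes, input %d x 1, trained %d epochs on %d spikes\n",
              x$spec$n_classes, x$spec$input_length, nrow(h), x$n_train))
  cat(sprintf("  final train loss %.5f, train accuracy %.4f\n",
              h$train_loss[nrow(h)], h$train_accuracy[nrow(h)]))
  if (!all(is.na(h$monitor_loss))) {
    cat(sprintf("  final monitor loss %.5f, monitor accuracy %.4f\n",
                h$monitor_loss[nrow(h)], h$monitor_accuracy[nrow(h)]))
  }
  invisible(x)
}

#' Predict spike cluster labels or probabilities
#'
#' @param object A fitted [train_cnn()] model.
#' @param newdata Waveform tibble (the `label` column, if present, is
#'   ignored).
#' @param type `"class"` for hard labels, `"prob"` for a tibble of
#'   per-class probabilities (columns `.pred_<label>`, rows summing to 1).
#' @param ... Unused.
#' @return Integer labels, or a probability tibble.
#' @export
predict.spike_cnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- waveform_matrix(newdata)
  if (ncol(x) != object$spec$input_length) {
    abort(sprintf("input has %d sample points; the model expects %d",
                  ncol(x), object$spec$input_length))
  }
  x <- (x - object$standardization$mean) / object$standardization$sd
  compiled <- compile_spec(object$spec)
  p <- .cnn_forward_probs(x, compiled$meta, compiled$drop, object$params,
                          object$bn_rmu, object$bn_rv, object$spec$n_classes)
  if (type == "prob") {
    colnames(p) <- paste0(".pred_", object$classes)
    return(tibble::as_tibble(p))
  }
  object$classes[max.col(p)]
}

#' Persist and restore a fitted model
#'
#' `save_spike_cnn()` writes a model directory holding `model.json` (the
#' architecture, label map, standardization statistics, training config and
#' history) and `weights.rds` (the flat parameter vector and
#' batch-normalization running statistics in R's native serialization).
#' `load_spike_cnn()` restores a model that predicts identically.
#'
#' @param model A fitted `spike_cnn`.
#' @param dir Directory to write/read.
#' @return `save_spike_cnn()` returns `dir` invisibly; `load_spike_cnn()`
#'   the restored model.
#' @export
save_spike_cnn <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(spec = list(input_length = model$spec$input_length,
                           n_classes = model$spec$n_classes,
                           layers = model$spec$layers),
               classes = model$classes,
               standardization = model$standardization,
               config = unclass(model$config),
               n_train = model$n_train,
               history = model$history)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(list(params = model$params, bn_rmu = model$bn_rmu,
               bn_rv = model$bn_rv,
               standardization = model$standardization),
          file.path(dir, "weights.rds"))
  invisible(dir)
}

#' @rdname save_spike_cnn
#' @export
load_spike_cnn <- function(dir) {
  mj <- file.path(dir, "model.json")
  wr <- file.path(dir, "weights.rds")
  if (!file.exists(mj) || !file.exists(wr)) {
    abort(sprintf("%s is not a model directory (model.json/weights.rds missing)", dir))
  }
  meta <- jsonlite::read_json(mj, simplifyVector = TRUE)
  spec <- build_model_spec(meta$spec$input_length, meta$spec$n_classes)
  # restore the exact layer list (covers non-default filters/options)
  spec$layers <- purrr::map(seq_len(nrow(meta$spec$layers)), function(i) {
    ly <- as.list(meta$spec$layers[i, ])
    Filter(function(v) !is.null(v) && !is.na(v), ly)
  })
  spec$layers <- purrr::map(spec$layers, function(ly) {
    for (f in c("filters", "kernel", "stride", "units")) {
      if (!is.null(ly[[f]])) ly[[f]] <- as.integer(ly[[f]])
    }
    ly
  })
  spec$shapes <- spec_shapes(spec)
  w <- readRDS(wr)
  cfg <- do.call(training_config, meta$config[names(meta$config) %in%
                                                names(formals(training_config))])
  structure(list(spec = spec, config = cfg,
                 classes = as.integer(meta$classes),
                 params = w$params, bn_rmu = w$bn_rmu, bn_rv = w$bn_rv,
                 standardization = w$standardization,
                 history = tibble::as_tibble(meta$history),
                 n_train = meta$n_train),
            class = "spike_cnn")
}

#' Tidy and summarize fitted spike classifiers
#'
#' `tidy()` returns the per-epoch training history in long-friendly wide
#' form; `glance()` a one-row model summary.
#'
#' @param x A fitted `spike_cnn`.
#' @param ... Unused.
#' @export
tidy.spike_cnn <- function(x, ...) x$history

#' @rdname tidy.spike_cnn
#' @export
glance.spike_cnn <- function(x, ...) {
  h <- x$history
  tibble::tibble(n_classes = x$spec$n_classes,
                 input_length = x$spec$input_length,
                 n_parameters = count_parameters(x$spec),
                 n_train = x$n_train,
                 epochs = nrow(h),
                 final_train_loss = h$train_loss[nrow(h)],
                 final_train_accuracy = h$train_accuracy[nrow(h)],
                 final_monitor_loss = h$monitor_loss[nrow(h)],
                 final_monitor_accuracy = h$monitor_accuracy[nrow(h)])
}

#' Loss-curve plot for a fitted model
#'
#' Plots per-epoch training (and, when a monitor set was supplied,
#' monitoring) cross-entropy.
#'
#' @param object A fitted `spike_cnn`.
#' @param ... Unused.
#' @export
autoplot.spike_cnn <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           dplyr::any_of(c("train_loss", "monitor_loss")),
                           names_to = "set", values_to = "loss")
  h <- dplyr::filter(h, !is.na(.data$loss))
  h$set <- sub("_loss$", "", h$set)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss", colour = NULL) +
    ggplot2::theme_minimal()
}
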