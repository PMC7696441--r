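#' Declare the 1D-CNN spike classifier architecture
#'
#' Builds the layer list of the network: four convolutional layers (kernel
#' 3, stride 1, zero "same" padding), two max-pooling layers, and a
#' three-layer fully connected head ending in a softmax over the classes.
#' The canonical sequence is
#'
#' `conv(32)+BN+ReLU -> conv(64)+ReLU -> maxpool -> conv(64)+ReLU ->
#' maxpool -> conv(32)+ReLU -> flatten -> dropout(0.5) -> dense(300)+ReLU ->
#' dense(100)+ReLU -> dense(n_classes)+softmax`
#'
#' so ReLU sits on layers 1, 2, 4, 6, 7 and 8 and softmax on layer 9. With
#' `pooling = "halve"` (the default) each pooling stage uses kernel 2 /
#' stride 2 and halves the signal length, which is the only geometry
#' consistent with a 32-position by 64-channel feature map after the first
#' pooling of a 64-sample input. `pooling = "slide"` instead uses kernel 3 /
#' stride 1 (a length-preserving variant described in prose accounts of
#' this architecture; it trains noticeably slower since nothing shrinks).
#'
#' @param input_length Samples per spike (64 for the simulated benchmark,
#'   12 for the experimental one). Must be at least 8 with `"halve"`
#'   pooling so two halvings leave at least 2 positions.
#' @param n_classes Number of spike clusters (at least 2).
#' @param conv_filters Filter counts of the four convolutional layers.
#' @param dense_units Unit counts of the first two dense layers.
#' @param dropout_rate Dropout rate between flatten and the dense head.
#' @param batch_norm `"first"` applies batch normalization after the first
#'   convolution only; `"all"` after every convolution; `"none"` disables it.
#' @param pooling Pooling geometry, see above.
#' @return A `cnn_spec` object: layer descriptors plus per-layer output
#'   shapes.
#' @examples
#' spec <- build_model_spec(64, 3)
#' spec
#' count_parameters(spec)
#' @export
build_model_spec <- function(input_length, n_classes,
                             conv_filters = c(32L, 64L, 64L, 32L),
                             dense_units = c(300L, 100L),
                             dropout_rate = 0.5,
                             batch_norm = c("first", "all", "none"),
                             pooling = c("halve", "slide")) {
  batch_norm <- match.arg(batch_norm)
  pooling <- match.arg(pooling)
  if (n_classes < 2L) abort("n_classes must be at least 2")
  pk <- if (pooling == "halve") 2L else 3L
  ps <- if (pooling == "halve") 2L else 1L
  min_len <- if (pooling == "halve") 8L else 5L
  if (input_length < min_len) {
    abort(sprintf("input_length %d is too short: two pooling stages (kernel %d, stride %d) need at least %d samples",
                  input_length, pk, ps, min_len))
  }
  stopifnot(length(conv_filters) == 4L, length(dense_units) == 2L,
            dropout_rate >= 0, dropout_rate < 1)

  conv <- function(f, bn) list(kind = "conv1d", filters = as.integer(f),
                               kernel = 3L, stride = 1L, padding = "same",
                               activation = "relu", batch_norm = bn)
  pool <- function() list(kind = "maxpool1d", kernel = pk, stride = ps)
  dense <- function(u, act) list(kind = "dense", units = as.integer(u),
                                 activation = act)
  layers <- list(
    conv(conv_filters[1L], batch_norm %in% c("first", "all")),
    conv(conv_filters[2L], batch_norm == "all"),
    pool(),
    conv(conv_filters[3L], batch_norm == "all"),
    pool(),
    conv(conv_filters[4L], batch_norm == "all"),
    list(kind = "flatten"),
    list(kind = "dropout", dropout_rate = dropout_rate),
    dense(dense_units[1L], "relu"),
    dense(dense_units[2L], "relu"),
    dense(n_classes, "softmax")
  )
  spec <- structure(list(input_length = as.integer(input_length),
                         n_classes = as.integer(n_classes),
                         layers = layers),
                    class = "cnn_spec")
  spec$shapes <- spec_shapes(spec)
  spec
}

# per-layer output shapes (length, channels); flat layers have channels = NA
spec_shapes <- function(spec) {
  l <- spec$input_length; c <- 1L
  flat <- FALSE; width <- NA_integer_
  out <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv1d") {
      c <- ly$filters
    } else if (ly$kind == "maxpool1d") {
      l2 <- (l - ly$kernel) %/% ly$stride + 1L
      if (l2 < 1L) abort(sprintf("layer %d: pooling reduces length %d below 1", i, l))
      l <- l2
    } else if (ly$kind == "flatten") {
      flat <- TRUE; width <- l * c
    } else if (ly$kind == "dense") {
      width <- ly$units
    }
    out[[i]] <- if (flat) list(width = width) else list(length = l, channels = c)
  }
  out
}

#' Count trainable parameters of a model spec
#'
#' Exact layer-by-layer count of weights, biases, and batch-normalization
#' scale/shift parameters.
#'
#' @param spec A [build_model_spec()] object.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  total <- 0L
  c_in <- 1L; l <- spec$input_length; flat_width <- NA_integer_
  for (ly in spec$layers) {
    if (ly$kind == "conv1d") {
      total <- total + ly$kernel * c_in * ly$filters + ly$filters
      if (isTRUE(ly$batch_norm)) total <- total + 2L * ly$filters
      c_in <- ly$filters
    } else if (ly$kind == "maxpool1d") {
      l <- (l - ly$kernel) %/% ly$stride + 1L
    } else if (ly$kind == "flatten") {
      flat_width <- l * c_in
    } else if (ly$kind == "dense") {
      total <- total + flat_width * ly$units + ly$units
      flat_width <- ly$units
    }
  }
  as.integer(total)
}

#' @export
print.cnn_spec <- function(x, ...) {
  cat(sprintf("<cnn_spec> input %d x 1, %d classes, %s parameters\n",
              x$input_length, x$n_classes,
              format(count_parameters(x), big.mark = ",")))
  for (i in seq_along(x$layers)) {
    ly <- x$layers[[i]]
    sh <- x$shapes[[i]]
    shape <- if (!is.null(sh$width)) sprintf("%d", sh$width)
             else sprintf("%d x %d", sh$length, sh$channels)
    desc <- switch(ly$kind,
      conv1d = sprintf("conv1d(%d, k=%d, same)%s + %s", ly$filters, ly$kernel,
                       if (isTRUE(ly$batch_norm)) " + BN" else "", ly$activation),
      maxpool1d = sprintf("maxpool(k=%d, stride=%d)", ly$kernel, ly$stride),
      flatten = "flatten",
      dropout = sprintf("dropout(%.2f)", ly$dropout_rate),
      dense = sprintf("dense(%d) + %s", ly$units, ly$activation))
    cat(sprintf("  %2d: %-32s -> %s\n", i, desc, shape))
  }
  invisible(x)
}

# compile a cnn_spec into the flat engine description:
# integer meta matrix (one row per engine layer), drop rates, parameter
# offsets (0-based) and total counts. Kinds: 1 conv, 2 pool, 3 flatten,
# 4 dropout, 5 dense.
compile_spec <- function(spec) {
  rows <- list(); drop <- numeric(0)
  off <- 0L; bn_off <- 0L
  l <- spec$input_length; c_in <- 1L; width <- NA_integer_
  for (ly in spec$layers) {
    r <- c(kind = 0L, lin = l, cin = c_in, cout = 0L, relu = 0L, bn = 0L,
           pk = 0L, ps = 0L, woff = 0L, boff = 0L, goff = 0L, beoff = 0L,
           soff = 0L, lout = l)
    dr <- 0
    if (ly$kind == "conv1d") {
      r["kind"] <- 1L; r["cout"] <- ly$filters
      r["relu"] <- as.integer(identical(ly$activation, "relu"))
      r["woff"] <- off; off <- off + 3L * c_in * ly$filters
      r["boff"] <- off; off <- off + ly$filters
      if (isTRUE(ly$batch_norm)) {
        r["bn"] <- 1L
        r["goff"] <- off; off <- off + ly$filters
        r["beoff"] <- off; off <- off + ly$filters
        r["soff"] <- bn_off; bn_off <- bn_off + ly$filters
      }
      c_in <- ly$filters
    } else if (ly$kind == "maxpool1d") {
      r["kind"] <- 2L; r["pk"] <- ly$kernel; r["ps"] <- ly$stride
      r["lout"] <- (l - ly$kernel) %/% ly$stride + 1L
      l <- r[["lout"]]
    } else if (ly$kind == "flatten") {
      r["kind"] <- 3L
      width <- l * c_in
    } else if (ly$kind == "dropout") {
      r["kind"] <- 4L
      dr <- ly$dropout_rate
    } else if (ly$kind == "dense") {
      r["kind"] <- 5L; r["cin"] <- width; r["cout"] <- ly$units
      r["relu"] <- as.integer(identical(ly$activation, "relu"))
      r["woff"] <- off; off <- off + width * ly$units
      r["boff"] <- off; off <- off + ly$units
      width <- ly$units
    } else {
      abort(sprintf("unknown layer kind '%s'", ly$kind))
    }
    rows[[length(rows) + 1L]] <- r
    drop <- c(drop, dr)
  }
  meta <- do.call(rbind, rows)
  storage.mode(meta) <- "integer"
  list(meta = meta, drop = drop, n_params = off, n_bn = bn_off)
}

# seeded parameter initialization: He for ReLU layers, Xavier for the head
init_params <- function(spec, compiled) {
  p <- numeric(compiled$n_params)
  meta <- compiled$meta
  for (i in seq_len(nrow(meta))) {
    kind <- meta[i, "kind"]
    if (kind == 1L) {
      fan_in <- 3L * meta[i, "cin"]
      nw <- fan_in * meta[i, "cout"]
      p[meta[i, "woff"] + seq_len(nw)] <- rnorm(nw, 0, sqrt(2 / fan_in))
      if (meta[i, "bn"] == 1L) {
        p[meta[i, "goff"] + seq_len(meta[i, "cout"])] <- 1
      }
    } else if (kind == 5L) {
      fan_in <- meta[i, "cin"]
      nw <- fan_in * meta[i, "cout"]
      sdv <- if (meta[i, "relu"] == 1L) sqrt(2 / fan_in) else sqrt(1 / fan_in)
      p[meta[i, "woff"] + seq_len(nw)] <- rnorm(nw, 0, sdv)
    }
  }
  p
}
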