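#' Labeled waveform tables
#'
#' Throughout the package a set of labeled spike waveforms is a tibble in
#' which the first column, `label`, holds a positive integer cluster id and
#' the remaining columns `s0, s1, ..., s{m-1}` hold the `m` amplitude samples
#' of each snippet (one spike per row). `waveform_tbl()` builds such a tibble
#' from a numeric matrix and a label vector; `waveform_matrix()` and
#' `waveform_labels()` go the other way.
#'
#' @param x For `waveform_tbl()`, a numeric matrix with one spike per row.
#'   For the accessors, a waveform tibble.
#' @param labels Integer vector of cluster ids (one per row of `x`).
#' @return `waveform_tbl()` returns a tibble with columns `label`,
#'   `s0..s{m-1}`; `waveform_matrix()` a numeric matrix; `waveform_labels()`
#'   an integer vector.
#' @examples
#' w <- waveform_tbl(matrix(rnorm(12), 3, 4), labels = c(1L, 2L, 1L))
#' waveform_matrix(w)
#' waveform_labels(w)
#' @export
waveform_tbl <- function(x, labels) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) storage.mode(x) <- "double" # empty frames coerce to logical
  if (!is.numeric(x)) abort("waveform data must be numeric")
  if (anyNA(x)) abort("waveform data contains missing values")
  if (length(labels) != nrow(x)) {
    abort(sprintf("got %d labels for %d waveforms", length(labels), nrow(x)))
  }
  check_labels(labels)
  colnames(x) <- paste0("s", seq_len(ncol(x)) - 1L)
  dplyr::bind_cols(tibble::tibble(label = as.integer(labels)),
                   tibble::as_tibble(x))
}

#' @rdname waveform_tbl
#' @export
waveform_matrix <- function(x) {
  nm <- sample_cols(x)
  m <- as.matrix(x[nm])
  if (!is.numeric(m)) abort("waveform sample columns must be numeric")
  if (anyNA(m)) abort("waveform data contains missing values")
  unname(m)
}

#' @rdname waveform_tbl
#' @export
waveform_labels <- function(x) {
  if (!"label" %in% names(x)) abort("no `label` column found")
  check_labels(x$label)
  as.integer(x$label)
}

sample_cols <- function(x) {
  nm <- grep("^s[0-9]+$", names(x), value = TRUE)
  if (length(nm) == 0L) abort("no sample columns (s0, s1, ...) found")
  nm[order(as.integer(sub("^s", "", nm)))]
}

n_sample_points <- function(x) length(sample_cols(x))

check_labels <- function(labels) {
  if (anyNA(labels)) abort("labels contain missing values")
  if (any(labels != as.integer(labels))) abort("labels must be integers")
  if (any(labels < 1L)) abort("labels must be positive integers")
  invisible(labels)
}

# every class 1..K must appear; returns K
check_class_coverage <- function(labels) {
  k <- max(labels)
  missing <- setdiff(seq_len(k), unique(labels))
  if (length(missing) > 0L) {
    abort(sprintf("class %s absent from the labels (expected every class in 1..%d)",
                  paste(missing, collapse = ", "), k))
  }
  k
}
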