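#' Continuous extracellular recordings and ground truth
#'
#' A recording is a numeric amplitude trace plus its sampling rate; the
#' ground truth for a recording is a tibble with one row per spike, columns
#' `time` (0-based sample index of the snippet start) and `label` (positive
#' integer cluster id), ordered by strictly increasing `time`.
#'
#' @param samples Numeric vector of amplitudes.
#' @param sampling_rate_hz Sampling rate in Hz (24000 for the simulated
#'   benchmark datasets).
#' @return An object of class `spike_recording`.
#' @export
spike_recording <- function(samples, sampling_rate_hz = 24000) {
  if (length(samples) < 1L) abort("a recording needs at least one sample")
  if (!is.numeric(samples) || anyNA(samples)) {
    abort("recording samples must be numeric and complete")
  }
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0) {
    abort("sampling_rate_hz must be positive")
  }
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = sampling_rate_hz),
            class = "spike_recording")
}

#' @export
print.spike_recording <- function(x, ...) {
  cat(sprintf("<spike_recording> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' @param time Integer vector of 0-based spike times (strictly increasing).
#' @param label Integer vector of cluster ids, same length as `time`.
#' @rdname spike_recording
#' @export
ground_truth_tbl <- function(time, label) {
  if (length(time) != length(label)) {
    abort("spike times and labels must have the same length")
  }
  if (length(time) > 0L) {
    check_labels(label)
    if (any(diff(time) <= 0)) {
      abort("spike times must be strictly increasing",
            class = "spikecnn_validation_error")
    }
  }
  tibble::tibble(time = as.integer(time), label = as.integer(label))
}

#' Read a ground-truthed recording in the Wave_Clus MAT layout
#'
#' Reads a MAT v5 file holding a continuous voltage trace (`data`), the
#' ground-truth spike times (`spike_times`, 1-based sample indices as stored
#' by MATLAB) and their cluster labels (`spike_class`). Either of the latter
#' two may be stored as a plain vector or wrapped in a cell array (the
#' public benchmark files use cells); the first cell element is used. An
#' optional `sr` variable overrides the sampling rate.
#'
#' @param path Path to the `.mat` file.
#' @param sampling_rate_hz Sampling rate used when the file has no `sr`
#'   variable.
#' @return A list with elements `recording` (a [spike_recording()]) and
#'   `ground_truth` (a tibble with 0-based `time` and `label`).
#' @export
read_waveclus_mat <- function(path, sampling_rate_hz = 24000) {
  vars <- read_mat_v5(path)
  need <- c("data", "spike_times", "spike_class")
  missing <- setdiff(need, names(vars))
  if (length(missing) > 0L) {
    abort(sprintf("MAT file lacks required variable(s): %s",
                  paste(missing, collapse = ", ")),
          class = "spikecnn_format_error")
  }
  first_numeric <- function(v) {
    # cells either wrap the vector (take the first cell) or were squeezed
    # into one scalar per cell (flatten)
    while (is.list(v)) {
      if (all(vapply(v, function(e) is.numeric(e) && length(e) == 1L,
                     logical(1)))) {
        v <- unlist(v)
      } else {
        v <- v[[1L]]
      }
    }
    as.numeric(v)
  }
  times <- first_numeric(vars$spike_times)
  labels <- first_numeric(vars$spike_class)
  if (length(times) != length(labels)) {
    abort(sprintf("spike_times (%d) and spike_class (%d) differ in length",
                  length(times), length(labels)),
          class = "spikecnn_validation_error")
  }
  if (length(times) > 0L && any(diff(times) <= 0)) {
    abort("spike times in file are not strictly increasing",
          class = "spikecnn_validation_error")
  }
  sr <- if (!is.null(vars$sr)) as.numeric(vars$sr)[1L] else sampling_rate_hz
  list(recording = spike_recording(first_numeric(vars$data), sr),
       ground_truth = ground_truth_tbl(times - 1, labels))
}

#' Write a recording and its ground truth in the Wave_Clus MAT layout
#'
#' @param recording A [spike_recording()].
#' @param ground_truth Ground-truth tibble (0-based `time`, `label`); times
#'   are stored 1-based as MATLAB convention dictates.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_waveclus_mat <- function(recording, ground_truth, path) {
  write_mat_v5(list(data = recording$samples,
                    sr = recording$sampling_rate_hz,
                    spike_times = as.numeric(ground_truth$time) + 1,
                    spike_class = as.numeric(ground_truth$label)),
               path)
}

#' Cut fixed-length spike snippets out of a continuous recording
#'
#' For every ground-truth spike time `t`, the half-open window
#' `[t + offset, t + offset + window)` is sliced out of the trace (0-based
#' indexing). Spikes whose window would run past either end of the recording
#' are dropped, with an informative message stating the count.
#'
#' @param recording A [spike_recording()].
#' @param ground_truth Tibble with `time` (0-based) and `label` columns.
#' @param window Snippet length in samples (64 for the 24 kHz simulated
#'   data).
#' @param offset Position of the ground-truth time inside the window: 0
#'   (default) means the time marks the window start.
#' @param center_on_peak If `TRUE`, each retained window is re-centred on
#'   its absolute-amplitude peak (searched within the initial window) before
#'   slicing, which removes alignment jitter between datasets that stamp
#'   spike onset versus spike peak.
#' @return A waveform tibble ([waveform_tbl()]) with one row per retained
#'   spike, carrying a `dropped` attribute with the number of boundary
#'   spikes discarded.
#' @export
extract_spikes <- function(recording, ground_truth, window = 64L,
                           offset = 0L, center_on_peak = FALSE) {
  if (window < 1L) abort("window must be at least 1 sample")
  n <- length(recording$samples)
  if (window > n) abort(sprintf("window (%d) exceeds recording length (%d)",
                                window, n))
  start <- ground_truth$time + as.integer(offset)
  keep <- start >= 0L & start + window <= n
  dropped <- sum(!keep)
  if (dropped > 0L) {
    inform(sprintf("extract_spikes: dropped %d spike(s) whose window crosses a recording boundary",
                   dropped), class = "spikecnn_dropped_spikes")
  }
  start <- start[keep]
  labels <- ground_truth$label[keep]
  if (center_on_peak && length(start) > 0L) {
    start <- vapply(start, function(s) {
      w <- recording$samples[(s + 1L):(s + window)]
      peak <- which.max(abs(w)) - 1L
      s2 <- s + peak - window %/% 2L
      max(0L, min(s2, n - window))
    }, integer(1))
  }
  m <- matrix(0, length(start), window)
  for (i in seq_along(start)) {
    m[i, ] <- recording$samples[(start[i] + 1L):(start[i] + window)]
  }
  out <- waveform_tbl(m, if (length(start)) labels else integer(0))
  attr(out, "dropped") <- dropped
  out
}

#' Downsample spike waveforms by integer decimation
#'
#' Keeps every k-th sample so that `target_points` columns remain, where k
#' must be an exact divisor of the current number of sample points (column
#' `j` of the output is column `j * k` of the input, 0-based). No
#' anti-alias filtering is applied; pre-filter the waveforms first if
#' aliasing is a concern.
#'
#' @param data A waveform tibble.
#' @param target_points Number of sample points to keep (e.g. 16 to thin
#'   64-point snippets by a factor of 4).
#' @return A waveform tibble with `target_points` sample columns.
#' @export
downsample_waveforms <- function(data, target_points) {
  m <- n_sample_points(data)
  if (target_points < 1L || m %% target_points != 0L) {
    divs <- Filter(function(d) m %% d == 0L, seq_len(m))
    abort(sprintf("target_points (%d) must divide the %d sample points; valid targets: %s",
                  target_points, m, paste(divs, collapse = ", ")))
  }
  k <- m %/% target_points
  keep <- paste0("s", (seq_len(target_points) - 1L) * k)
  out <- data[c(if ("label" %in% names(data)) "label", keep)]
  names(out) <- c(if ("label" %in% names(data)) "label",
                  paste0("s", seq_len(target_points) - 1L))
  tibble::as_tibble(out)
}

#' Read and write labeled waveform tables
#'
#' The canonical on-disk interchange format for labeled spike sets: a
#' comma-separated table with header `label,s0,...,s{m-1}`, one spike per
#' row. Values round-trip at full double precision.
#'
#' @param data A waveform tibble ([waveform_tbl()]).
#' @param path File path.
#' @return `write_waveform_table()` returns `path` invisibly;
#'   `read_waveform_table()` returns a waveform tibble.
#' @export
write_waveform_table <- function(data, path) {
  stopifnot(is.data.frame(data))
  waveform_labels(data) # validates
  readr::write_csv(data[c("label", sample_cols(data))], path)
  invisible(path)
}

#' @rdname write_waveform_table
#' @export
read_waveform_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  suppressWarnings(
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  )
  pr <- readr::problems(x)
  if (nrow(pr) > 0L) {
    abort(sprintf("malformed waveform table %s (first problem at line %d: %s)",
                  path, pr$row[1L] + 1L, pr$expected[1L]),
          class = "spikecnn_format_error")
  }
  if (!"label" %in% names(x)) {
    abort("waveform table lacks a `label` column", class = "spikecnn_format_error")
  }
  if (nrow(x) > 0L && any(x$label != as.integer(x$label))) {
    abort("waveform table labels must be integers", class = "spikecnn_format_error")
  }
  waveform_tbl(as.matrix(x[sample_cols(x)]), as.integer(x$label))
}
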