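#' Configuration for a synthetic extracellular recording
#'
#' Bundles the knobs of the recording simulator. Defaults describe the
#' reference condition used throughout the package: three units firing at
#' 20 Hz each for 60 s at 24 kHz (roughly 3400 spikes of 64 samples), a 3 ms
#' refractory period, and background noise assembled from spike shapes
#' superimposed at 2000 events/s, scaled to a noise level of 0.15.
#'
#' The noise level is defined as the standard deviation of the background
#' noise divided by the mean template peak amplitude; since templates are
#' peak-normalized to 1, the background trace is rescaled so its standard
#' deviation equals `noise_level` exactly.
#'
#' @param n_classes Number of units.
#' @param n_samples_per_spike Snippet length in samples.
#' @param sampling_rate_hz Sampling rate in Hz.
#' @param duration_s Recording duration in seconds.
#' @param firing_rate_hz Per-class rate of the exponential inter-spike
#'   process (a refractory dead time is added on top, so the realized rate
#'   is `1 / (refractory_s + 1/firing_rate_hz)`).
#' @param noise_level Background noise level in `[0, 1)`; the benchmark
#'   range is 0.05-0.4.
#' @param refractory_samples Minimum same-class inter-spike interval in
#'   samples (72 samples = 3 ms at 24 kHz).
#' @param noise_superposition_rate_hz Rate of the background spike-shape
#'   superposition process.
#' @param amplitude_jitter Foreground amplitudes are drawn uniformly in
#'   `1 +/- amplitude_jitter`.
#' @param noise_amp_range Range of the uniform background superposition
#'   amplitudes (before global rescaling).
#' @param seed Integer seed controlling all randomness downstream.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_classes = 3L, n_samples_per_spike = 64L,
                              sampling_rate_hz = 24000, duration_s = 60,
                              firing_rate_hz = 20, noise_level = 0.15,
                              refractory_samples = 72L,
                              noise_superposition_rate_hz = 2000,
                              amplitude_jitter = 0.1,
                              noise_amp_range = c(0.5, 1),
                              seed = 1L) {
  if (noise_level < 0 || noise_level >= 1) abort("noise_level must be in [0, 1)")
  if (any(firing_rate_hz <= 0)) abort("firing rates must be positive")
  if (duration_s <= 0) abort("duration_s must be positive")
  rates <- rep_len(firing_rate_hz, n_classes)
  expected <- duration_s / (refractory_samples / sampling_rate_hz + 1 / rates)
  if (any(expected < 1)) {
    abort("duration too short for at least one expected spike per class")
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_samples_per_spike = as.integer(n_samples_per_spike),
                 sampling_rate_hz = sampling_rate_hz,
                 duration_s = duration_s,
                 firing_rate_hz = rates,
                 noise_level = noise_level,
                 refractory_samples = as.integer(refractory_samples),
                 noise_superposition_rate_hz = noise_superposition_rate_hz,
                 amplitude_jitter = amplitude_jitter,
                 noise_amp_range = noise_amp_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected foreground spike count of a configuration
#'
#' Closed form for the dead-time point process used by the simulator: each
#' class fires with inter-spike intervals `refractory + Exp(rate)`, so the
#' expected total count is `sum(duration / (refractory_s + 1/rate))`.
#'
#' @param config A [simulation_config()].
#' @return Expected number of foreground spikes (all classes).
#' @export
expected_spike_count <- function(config) {
  refr_s <- config$refractory_samples / config$sampling_rate_hz
  sum(config$duration_s / (refr_s + 1 / config$firing_rate_hz))
}

#' Synthesize a ground-truthed extracellular recording
#'
#' Builds a continuous trace the way the classic simulated spike-sorting
#' benchmark is built: per-class spike trains are drawn as Poisson processes
#' with an enforced refractory dead time and amplitude jitter, template
#' waveforms are added at the spike times, and background noise is created
#' by superimposing randomly chosen templates at Poisson times with random
#' amplitudes, then rescaled so that `sd(noise) / mean peak amplitude`
#' equals the configured noise level.
#'
#' @param bank A [make_templates()] bank with `config$n_classes` templates.
#' @param config A [simulation_config()].
#' @return A `spike_simulation`: list with `recording`
#'   ([spike_recording()]), `ground_truth` (tibble of 0-based `time`,
#'   `label`), `templates`, `realized_noise_level`, `n_overlapped` (pairs of
#'   foreground spikes closer than one snippet), and `components`
#'   (`foreground` and `noise` traces, summing to the recording).
#' @export
synthesize_recording <- function(bank, config = simulation_config()) {
  stopifnot(inherits(bank, "template_bank"))
  if (nrow(bank$templates) != config$n_classes) {
    abort(sprintf("bank has %d templates but config expects %d classes",
                  nrow(bank$templates), config$n_classes))
  }
  if (ncol(bank$templates) != config$n_samples_per_spike) {
    abort("template length does not match n_samples_per_spike")
  }
  fs <- config$sampling_rate_hz
  n <- as.integer(round(config$duration_s * fs))
  win <- config$n_samples_per_spike

  local_seeded(config$seed, {
    ## foreground spike trains: dead-time Poisson per class
    times <- integer(0); labels <- integer(0)
    for (k in seq_len(config$n_classes)) {
      gaps_s <- NULL
      t_k <- integer(0)
      t_cur <- 0
      rate <- config$firing_rate_hz[k]
      repeat {
        t_cur <- t_cur + config$refractory_samples + round(rexp(1, rate) * fs)
        if (t_cur > n - win) break
        t_k <- c(t_k, as.integer(t_cur))
      }
      times <- c(times, t_k)
      labels <- c(labels, rep(k, length(t_k)))
    }
    if (length(times) == 0L) abort("duration too short: no spikes generated")
    ord <- order(times, labels)
    times <- times[ord]; labels <- labels[ord]
    ## resolve exact collisions between classes so ground truth is strictly
    ## increasing (shift the later class by one sample)
    while (anyDuplicated(times)) {
      i <- which(duplicated(times))
      times[i] <- times[i] + 1L
      ord <- order(times, labels)
      times <- times[ord]; labels <- labels[ord]
      keep <- times <= n - win
      times <- times[keep]; labels <- labels[keep]
    }

    foreground <- numeric(n)
    amps <- runif(length(times), 1 - config$amplitude_jitter,
                  1 + config$amplitude_jitter)
    for (i in seq_along(times)) {
      idx <- (times[i] + 1L):(times[i] + win)
      foreground[idx] <- foreground[idx] + amps[i] * bank$templates[labels[i], ]
    }

    ## background: spike shapes at Poisson times, random amplitudes
    noise <- numeric(n)
    if (config$noise_level > 0) {
      n_events <- stats::rpois(1, config$noise_superposition_rate_hz *
                                    (n + win) / fs)
      ev_start <- sample.int(n + win, n_events, replace = TRUE) - win # 0-based
      ev_class <- sample.int(config$n_classes, n_events, replace = TRUE)
      ev_amp <- runif(n_events, config$noise_amp_range[1L],
                      config$noise_amp_range[2L])
      for (i in seq_len(n_events)) {
        idx <- (ev_start[i] + 1L):(ev_start[i] + win)
        ok <- idx >= 1L & idx <= n
        if (!any(ok)) next
        noise[idx[ok]] <- noise[idx[ok]] +
          ev_amp[i] * bank$templates[ev_class[i], ok]
      }
      s <- sd(noise)
      if (s > 0) noise <- noise * (config$noise_level / s)
    }

    mean_peak <- mean(apply(abs(bank$templates), 1L, max)) # == 1 by construction
    realized <- if (config$noise_level > 0) sd(noise) / mean_peak else 0

    structure(list(
      recording = spike_recording(foreground + noise, fs),
      ground_truth = ground_truth_tbl(times, labels),
      templates = bank,
      realized_noise_level = realized,
      n_overlapped = sum(diff(times) < win),
      components = list(foreground = foreground, noise = noise),
      config = config
    ), class = "spike_simulation")
  })
}

#' @export
print.spike_simulation <- function(x, ...) {
  cat(sprintf("<spike_simulation> %d spikes / %d classes, %.1f s @ %g Hz\n",
              nrow(x$ground_truth), x$config$n_classes, x$config$duration_s,
              x$config$sampling_rate_hz))
  cat(sprintf("  difficulty %s, noise level %.3f (realized %.3f), %d overlapped pair(s)\n",
              x$templates$difficulty, x$config$noise_level,
              x$realized_noise_level, x$n_overlapped))
  invisible(x)
}

#' Generate a ready-to-train labeled spike set
#'
#' One-call composition of [make_templates()], [synthesize_recording()] and
#' [extract_spikes()]: simulates a recording and cuts the labeled snippets
#' at the ground-truth times. Metadata (config, difficulty, realized noise
#' level, overlap count, seed) is attached as the `sim_info` attribute and
#' retrievable with [sim_info()].
#'
#' @param config A [simulation_config()].
#' @param difficulty Template likeness mode, `"easy"` or `"difficult"`.
#' @return A waveform tibble with one row per simulated spike.
#' @examples
#' spikes <- generate_labeled_set(simulation_config(duration_s = 2), "easy")
#' dplyr::count(spikes, label)
#' @export
generate_labeled_set <- function(config = simulation_config(),
                                 difficulty = c("easy", "difficult")) {
  difficulty <- match.arg(difficulty)
  bank <- make_templates(config$n_classes, config$n_samples_per_spike,
                         difficulty, seed = config$seed)
  sim <- synthesize_recording(bank, config)
  out <- extract_spikes(sim$recording, sim$ground_truth,
                        window = config$n_samples_per_spike, offset = 0L)
  attr(out, "sim_info") <- list(config = config, difficulty = difficulty,
                                seed = config$seed,
                                realized_noise_level = sim$realized_noise_level,
                                n_overlapped = sim$n_overlapped)
  out
}

#' @rdname generate_labeled_set
#' @param data A waveform tibble produced by [generate_labeled_set()].
#' @export
sim_info <- function(data) attr(data, "sim_info")

#' Write a simulated dataset to disk
#'
#' Writes the labeled snippets as the canonical waveform table, a JSON
#' sidecar with the simulation metadata, and optionally the continuous
#' recording in the Wave_Clus MAT layout for cross-tool use.
#'
#' @param sim A `spike_simulation` from [synthesize_recording()].
#' @param dir Output directory (created if missing).
#' @param name Basename for the files.
#' @param mat Also write `<name>.mat` with the continuous recording.
#' @return Named character vector of the files written.
#' @export
write_simulated_dataset <- function(sim, dir, name = "simulated", mat = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spikes <- extract_spikes(sim$recording, sim$ground_truth,
                           window = sim$config$n_samples_per_spike)
  files <- c(table = file.path(dir, paste0(name, ".csv")),
             sidecar = file.path(dir, paste0(name, ".json")))
  write_waveform_table(spikes, files[["table"]])
  jsonlite::write_json(list(config = unclass(sim$config),
                            difficulty = sim$templates$difficulty,
                            seed = sim$config$seed,
                            realized_noise_level = sim$realized_noise_level,
                            n_overlapped = sim$n_overlapped,
                            n_spikes = nrow(sim$ground_truth)),
                       files[["sidecar"]], auto_unbox = TRUE, digits = NA)
  if (mat) {
    files <- c(files, mat = file.path(dir, paste0(name, ".mat")))
    write_waveclus_mat(sim$recording, sim$ground_truth, files[["mat"]])
  }
  files
}
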