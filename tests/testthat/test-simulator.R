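test_that("a zero-noise recording reproduces the placed templates exactly", {
  bank <- make_templates(3, 64, "easy", seed = 4)
  cfg <- simulation_config(duration_s = 2, noise_level = 0, seed = 4)
  sim <- synthesize_recording(bank, cfg)
  gt <- sim$ground_truth
  # non-overlapped spikes: neighbours at least one window away
  gaps_ok <- c(diff(gt$time) >= 64, TRUE) & c(TRUE, diff(gt$time) >= 64)
  w <- extract_spikes(sim$recording, gt[gaps_ok, ], window = 64L)
  m <- waveform_matrix(w)
  y <- waveform_labels(w)
  for (i in seq_len(nrow(m))) {
    tpl <- bank$templates[y[i], ]
    amp <- m[i, which.max(abs(tpl))] / tpl[which.max(abs(tpl))]
    expect_true(amp >= 0.9 && amp <= 1.1)          # amplitude jitter bounds
    expect_equal(m[i, ], amp * tpl, tolerance = 1e-12)
  }
})

test_that("the recording decomposes exactly into foreground plus noise", {
  bank <- make_templates(3, 64, "easy", seed = 5)
  sim <- synthesize_recording(bank, simulation_config(duration_s = 1, seed = 5))
  resid <- sim$recording$samples -
    (sim$components$foreground + sim$components$noise)
  expect_lt(max(abs(resid)), 1e-6)
})

test_that("the realized noise level matches the configured level", {
  # the background is rescaled to the target level, so each realization is
  # exact; check the measurement over several seeds anyway
  levels <- vapply(1:20, function(s) {
    bank <- make_templates(3, 64, "easy", seed = s)
    sim <- synthesize_recording(bank,
      simulation_config(duration_s = 0.5, noise_level = 0.15, seed = s))
    sim$realized_noise_level
  }, numeric(1))
  expect_true(all(abs(levels - 0.15) / 0.15 <= 0.1))
  expect_lt(abs(mean(levels) - 0.15) / 0.15, 0.05)
  # the measured quantity is sd(noise component) / unit template peak
  bank <- make_templates(3, 64, "easy", seed = 21)
  sim <- synthesize_recording(bank,
    simulation_config(duration_s = 0.5, noise_level = 0.15, seed = 21))
  expect_equal(sd(sim$components$noise), 0.15, tolerance = 1e-12)
})

test_that("same-class spikes respect the refractory dead time", {
  bank <- make_templates(3, 64, "easy", seed = 6)
  cfg <- simulation_config(duration_s = 5, seed = 6, refractory_samples = 72L)
  sim <- synthesize_recording(bank, cfg)
  for (k in 1:3) {
    t_k <- sim$ground_truth$time[sim$ground_truth$label == k]
    if (length(t_k) > 1) expect_true(all(diff(t_k) >= 72))
  }
})

test_that("spike counts follow the dead-time Poisson expectation", {
  # rate chosen so the closed-form expectation is ~3477 spikes in 60 s
  cfg <- simulation_config(duration_s = 60, firing_rate_hz = 20.502,
                           noise_level = 0, seed = 1)
  expect_equal(expected_spike_count(cfg), 3477, tolerance = 0.001)
  counts <- vapply(1:3, function(s) {
    bank <- make_templates(3, 64, "easy", seed = s)
    cfg$seed <- s
    nrow(synthesize_recording(bank, cfg)$ground_truth)
  }, numeric(1))
  expect_true(all(abs(counts - 3477) / 3477 <= 0.1))
})

test_that("overlapped foreground spikes are counted and kept", {
  bank <- make_templates(3, 64, "easy", seed = 7)
  sim <- synthesize_recording(bank, simulation_config(duration_s = 2, seed = 7))
  gt <- sim$ground_truth
  expect_identical(sim$n_overlapped, sum(diff(gt$time) < 64L))
  expect_true(all(diff(gt$time) > 0))             # strictly increasing
  expect_true(all(gt$label %in% 1:3))
})

test_that("generate_labeled_set is deterministic and carries metadata", {
  cfg <- simulation_config(duration_s = 1, seed = 11)
  a <- generate_labeled_set(cfg, "easy")
  b <- generate_labeled_set(cfg, "easy")
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_setequal(unique(a$label), 1:3)
  expect_equal(ncol(waveform_matrix(a)), 64L)
  info <- sim_info(a)
  expect_equal(info$seed, 11L)
  expect_equal(info$difficulty, "easy")
  expect_true(is.numeric(info$realized_noise_level))
  five <- generate_labeled_set(simulation_config(duration_s = 2, n_classes = 5,
                                                 seed = 3), "easy")
  expect_setequal(unique(five$label), 1:5)
})

test_that("simulation configs validate their ranges", {
  expect_error(simulation_config(noise_level = 1.5), "noise_level")
  expect_error(simulation_config(firing_rate_hz = 0), "positive")
  expect_error(simulation_config(duration_s = 0.001), "too short")
})

test_that("simulated datasets write a table, sidecar, and optional MAT file", {
  bank <- make_templates(3, 64, "easy", seed = 8)
  sim <- synthesize_recording(bank, simulation_config(duration_s = 0.5, seed = 8))
  dir <- withr::local_tempdir()
  files <- suppressMessages(write_simulated_dataset(sim, dir, mat = TRUE))
  expect_true(all(file.exists(files)))
  sidecar <- jsonlite::read_json(files[["sidecar"]])
  expect_equal(sidecar$seed, 8L)
  expect_equal(sidecar$n_spikes, nrow(sim$ground_truth))
  back <- read_waveclus_mat(files[["mat"]])
  expect_equal(back$recording$samples, sim$recording$samples)
})
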