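test_that("schedule generation places the requested events inside the trial", {
  expect_equal(nrow(generate_stimulus_schedule(
    sim_config(duration = 10, n_stimuli = 0))), 0)

  cfg <- sim_config(duration = 92, n_stimuli = 39, rng_seed = 2)
  sch <- generate_stimulus_schedule(cfg)
  expect_equal(nrow(sch), 39)
  expect_true(all(sch$true_offset <= 92 + 1e-9))
  expect_equal(sch$true_offset - sch$true_onset, rep(0.2, 39),
               tolerance = 1e-12)
  expect_equal(sch$logged_offset, sch$true_offset)
  # strictly ordered, non-overlapping
  expect_true(all(diff(sch$true_onset) > 0))
  expect_true(all(sch$true_onset[-1] >= sch$true_offset[-39]))
})

test_that("gap draws match an independent re-implementation of the sampler", {
  cfg <- sim_config(duration = 60, n_stimuli = 10, rng_seed = 77)
  sch <- generate_stimulus_schedule(cfg)
  # span bound from the gap model: each of the 10 gap+flash blocks is in
  # [2.2, 3.2] s
  expect_gte(tail(sch$true_offset, 1), 10 * 2.2)
  expect_lte(tail(sch$true_offset, 1), 10 * 3.2)
  # independent oracle: replay the truncated-uniform draws directly
  set.seed(flashvep:::child_seed(77L, 1L))
  t <- 0; onsets <- numeric(10)
  for (i in 1:10) {
    slack <- 60 - t - (10 - i) * 2.2 - 0.2
    onsets[i] <- t + runif(1, 2, min(3, max(2, slack)))
    t <- onsets[i] + 0.2
  }
  expect_equal(sch$true_onset, onsets)
})

test_that("infeasible stimulus programs are rejected", {
  expect_error(sim_config(duration = 20, n_stimuli = 39), "too short")
  expect_error(sim_config(duration = 100, n_stimuli = 10,
                          isi_range = c(3, 2)), "isi_range")
})

test_that("timing jitter is one-sided, bounded and mean max/2", {
  cfg <- sim_config(duration = 92, n_stimuli = 30, rng_seed = 5)
  sch <- generate_stimulus_schedule(cfg)

  same <- apply_timing_jitter(sch, 0, rng_seed = 1)
  expect_identical(same$logged_offset, sch$true_offset)

  jit <- apply_timing_jitter(sch, 0.25, rng_seed = 9)
  err <- jit$logged_offset - jit$true_offset
  expect_true(all(err >= 0 & err <= 0.25))
  expect_identical(jit$true_onset, sch$true_onset)

  # law of large numbers on the uniform error model, 10^4 draws
  big <- data.frame(true_onset = seq_len(1e4) * 3,
                    true_offset = seq_len(1e4) * 3 + 0.2,
                    logged_offset = seq_len(1e4) * 3 + 0.2,
                    intensity_db = 4)
  bjit <- apply_timing_jitter(big, 0.25, rng_seed = 10)
  berr <- bjit$logged_offset - bjit$true_offset
  expect_true(all(berr >= 0 & berr <= 0.25))
  se <- 0.25 / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(berr) - 0.125), 3 * se)

  sym <- apply_timing_jitter(big, 0.25, rng_seed = 11, symmetric = TRUE)
  serr <- sym$logged_offset - sym$true_offset
  expect_true(all(abs(serr) <= 0.25))
  expect_true(any(serr < 0))
})

test_that("evoked template has the configured component structure", {
  fs <- 250
  null_t <- synthesize_vep_template(
    list(latency = c(0.075, 0.1), amplitude = c(0, 0),
         width = c(0.02, 0.02)), fs)
  expect_true(all(null_t == 0))

  vp <- list(latency = c(0.075, 0.100, 0.135), amplitude = c(-2, 5, -3),
             width = c(0.020, 0.025, 0.030))
  tmpl <- synthesize_vep_template(vp, fs)
  # support ends before 300 ms + 3 widths
  expect_lte(length(tmpl) / fs, 0.3 + 3 * max(vp$width))
  expect_gt(sum(tmpl^2), 0)
  # largest positive deflection peaks at the configured latency
  expect_lte(abs((which.max(tmpl) - 1) / fs - 0.100), 1 / fs)
  expect_error(synthesize_vep_template(
    list(latency = 0.7, amplitude = 1, width = 0.02), fs), "0.6")
})

test_that("recording synthesis injects topography-scaled responses", {
  # silence: no noise, no artifacts, no response
  cfg0 <- sim_config(duration = 10, n_stimuli = 2, rng_seed = 1,
                     vep_params = list(latency = 0.1, amplitude = 0,
                                       width = 0.02),
                     noise_params = list(pink_sd = 0, pink_exponent = 1,
                                         alpha_sd = 0, alpha_freq = 10,
                                         blink_rate = 0, blink_amp = 0,
                                         muscle_rate = 0, muscle_amp = 0))
  sch0 <- generate_stimulus_schedule(cfg0)
  expect_true(all(simulate_recording(sch0, cfg0)$data == 0))

  # one event, occipital gain 1, parietal gain 0.2 -> 25x energy ratio
  cfg1 <- sim_config(duration = 10, n_stimuli = 1, rng_seed = 1,
                     intensity_db = 0,
                     topography = c(P3 = 0.2, P4 = 0.2, PO3 = 0.2, PO4 = 0.2,
                                    POz = 0.2, O1 = 1, O2 = 1, Oz = 1),
                     noise_params = list(pink_sd = 0, pink_exponent = 1,
                                         alpha_sd = 0, alpha_freq = 10,
                                         blink_rate = 0, blink_amp = 0,
                                         muscle_rate = 0, muscle_amp = 0))
  sch1 <- generate_stimulus_schedule(cfg1)
  rec1 <- simulate_recording(sch1, cfg1)
  expect_equal(sum(rec1$data["O1", ]^2) / sum(rec1$data["P3", ]^2), 25,
               tolerance = 1e-9)

  # 4 dB stimuli are injected with strictly larger amplitude than 16 dB
  mk <- function(db) {
    cfg <- sim_config(duration = 20, n_stimuli = 3, rng_seed = 4,
                      intensity_db = db,
                      noise_params = list(pink_sd = 0, pink_exponent = 1,
                                          alpha_sd = 0, alpha_freq = 10,
                                          blink_rate = 0, blink_amp = 0,
                                          muscle_rate = 0, muscle_amp = 0))
    simulate_recording(generate_stimulus_schedule(cfg), cfg)
  }
  expect_gt(max(abs(mk(4)$data)), max(abs(mk(16)$data)))
})

test_that("simulation is deterministic and superposition-exact", {
  cfg <- sim_config(duration = 30, n_stimuli = 8, rng_seed = 42)
  sch <- generate_stimulus_schedule(cfg)
  rec1 <- simulate_recording(sch, cfg)
  rec2 <- simulate_recording(sch, cfg)
  expect_identical(rec1$data, rec2$data)

  # noise-only run with the same seed: difference is exactly the sum of the
  # injected scaled templates
  cfg0 <- cfg
  cfg0$vep_params$amplitude <- cfg0$vep_params$amplitude * 0
  noise <- simulate_recording(sch, cfg0)
  injected <- rec1$data - noise$data
  fs <- cfg$sampling_rate
  tmpl <- synthesize_vep_template(cfg$vep_params, fs)
  expected <- matrix(0, nrow(rec1$data), ncol(rec1$data))
  gains <- cfg$topography[cfg$channel_labels]
  for (e in seq_len(nrow(sch))) {
    i0 <- floor(sch$true_onset[e] * fs + 0.5) + 1
    idx <- i0:min(ncol(expected), i0 + length(tmpl) - 1)
    expected[, idx] <- expected[, idx] +
      outer(unname(gains), tmpl[seq_along(idx)] *
              amplitude_scale(sch$intensity_db[e]))
  }
  expect_equal(unname(injected), expected, tolerance = 1e-12)
})

test_that("config and schedule round-trip through YAML and TSV", {
  cfg <- sim_config(duration = 30, n_stimuli = 5, rng_seed = 3)
  yml <- tempfile(fileext = ".yaml")
  write_sim_config_yaml(cfg, yml)
  cfg2 <- read_sim_config_yaml(yml)
  expect_equal(cfg2$duration, cfg$duration)
  expect_equal(cfg2$topography, cfg$topography)
  expect_equal(cfg2$vep_params, cfg$vep_params)

  sch <- generate_stimulus_schedule(cfg)
  sch <- apply_timing_jitter(sch, 0.25, rng_seed = 2)
  tsv <- tempfile(fileext = ".tsv")
  write_events_tsv(sch, tsv)
  expect_equal(read_events_tsv(tsv), sch, tolerance = 1e-12)
})
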