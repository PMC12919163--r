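make_schedule <- function(logged_offsets, stim_dur = 0.2) {
  data.frame(true_onset = logged_offsets - stim_dur,
             true_offset = logged_offsets,
             logged_offset = logged_offsets,
             intensity_db = rep(4, length(logged_offsets)))
}

test_that("segments are exactly 150 samples at 250 Hz", {
  rec <- toy_recording(n_channels = 2, n_samples = 2500, seed = 1)
  segs <- extract_segments(rec, make_schedule(c(3, 6)))
  expect_true(all(vapply(segs$segments, ncol, 1L) == 150))
  expect_equal(segs$window_samples, 150)
})

test_that("tiling matches an independent brute-force tiler on a toy case", {
  rec <- toy_recording(n_channels = 2, n_samples = 2500, seed = 1)  # 10 s
  sch <- make_schedule(c(3, 6))
  segs <- extract_segments(rec, sch)
  expect_equal(unname(class_counts(segs)["stimulus"]), 2L)

  oracle_w <- oracle_stim_windows(sch$logged_offset, 250, 150)
  oracle_n <- brute_force_tiling(2500, 150, oracle_w$start, oracle_w$end)
  got <- segs$info[segs$info$label == "non_stimulus", ]
  expect_equal(nrow(got), nrow(oracle_n))
  expect_equal(got$start_time * 250, oracle_n$start)
  expect_equal(150 - got$padded_samples, oracle_n$real_len)

  # stimulus windows land where the offset times say
  stim <- segs$info[segs$info$label == "stimulus", ]
  expect_equal(stim$start_time * 250, oracle_w$start)
})

test_that("empty schedules tile the whole recording as non-stimulus", {
  rec <- toy_recording(n_channels = 2, n_samples = 1500, seed = 2)
  segs <- extract_segments(rec, make_schedule(numeric(0)))
  expect_equal(unname(class_counts(segs)),
               c(0L, 10L))  # 1500 / 150 exact chunks
  expect_true(all(segs$info$padded_samples == 0))
})

test_that("overlapping stimulus windows are rejected, short gaps padded", {
  rec <- toy_recording(n_channels = 2, n_samples = 2500, seed = 3)
  expect_error(extract_segments(rec, make_schedule(c(3, 3.4))),
               "overlapping")

  # events closer than window + min sliver: gap of 0.3 s between windows
  # (75 samples = 50% of a window) is kept as one padded segment
  segs <- extract_segments(rec, make_schedule(c(3, 3.9)))
  gap_seg <- segs$info[segs$info$label == "non_stimulus" &
                         segs$info$start_time == 3.0, ]
  expect_equal(nrow(gap_seg), 1)
  expect_equal(gap_seg$padded_samples, 75)
})

test_that("sample conservation: no source sample is used twice", {
  rec <- toy_recording(n_channels = 2, n_samples = 2500, seed = 4)
  sch <- make_schedule(c(2.1, 4.63, 8.2))
  segs <- extract_segments(rec, sch)
  used <- integer(2500)
  for (i in seq_along(segs$segments)) {
    s0 <- round(segs$info$start_time[i] * 250)
    real <- 150 - segs$info$padded_samples[i]
    used[(s0 + 1):(s0 + real)] <- used[(s0 + 1):(s0 + real)] + 1L
  }
  expect_true(all(used <= 1))
  # and the real samples reproduce the source exactly
  i <- which(segs$info$label == "stimulus")[2]
  s0 <- round(segs$info$start_time[i] * 250)
  expect_equal(segs$segments[[i]], rec$data[, (s0 + 1):(s0 + 150)],
               ignore_attr = TRUE)
})

test_that("count law holds against brute force on random schedules", {
  set.seed(99)
  fs <- 250; ws <- 150
  for (rep in 1:20) {
    n <- sample(1500:4000, 1)
    n_ev <- sample(1:6, 1)
    offs <- sort(runif(n_ev, 0.7, n / fs - 0.1))
    offs <- offs[c(TRUE, diff(offs) > 0.7)]  # enforce non-overlap
    rec <- new_recording(matrix(rnorm(2 * n), 2), fs, c("a", "b"))
    segs <- extract_segments(rec, make_schedule(offs))
    ow <- oracle_stim_windows(offs, fs, ws)
    bf <- brute_force_tiling(n, ws, ow$start, ow$end)
    expect_equal(sum(segs$info$label == "non_stimulus"), nrow(bf))
    expect_equal(sum(segs$info$label == "stimulus"), length(offs))
  }
})

test_that("averaging excludes padding and recovers the injected response", {
  # mean of a single segment is the segment
  one <- make_segment_set(list(matrix(1:300, 2,
                                      dimnames = list(c("a", "b"), NULL))),
                          "stimulus")
  expect_equal(average_segments(one, "stimulus"),
               matrix(1:300, 2, dimnames = list(c("a", "b"), NULL)))

  # two opposite segments cancel
  x <- matrix(rnorm(300), 2, dimnames = list(c("a", "b"), NULL))
  two <- make_segment_set(list(x, -x), c("stimulus", "stimulus"))
  expect_equal(average_segments(two, "stimulus"),
               matrix(0, 2, 150, dimnames = list(c("a", "b"), NULL)),
               tolerance = 1e-12)
  expect_error(average_segments(two, "non_stimulus"), "no segments")

  # synthetic high-SNR, zero-jitter trial: the stimulus-class mean shows the
  # P100 peak at its injected latency; the non-stimulus mean is much smaller
  cfg <- sim_config(duration = 95, n_stimuli = 30, max_sync_error = 0,
                    rng_seed = 8,
                    noise_params = list(pink_sd = 0.4, pink_exponent = 1,
                                        alpha_sd = 0.2, alpha_freq = 10,
                                        blink_rate = 0, blink_amp = 0,
                                        muscle_rate = 0, muscle_amp = 0))
  sch <- generate_stimulus_schedule(cfg)
  rec <- simulate_recording(sch, cfg)
  segs <- extract_segments(rec, sch)
  avg <- average_segments(segs, "stimulus")
  # window is [offset - 0.6, offset); onset at offset - 0.2; P100 0.1 s
  # after onset -> 0.1 s before offset -> sample 150 - 25 = 125 (1-based)
  expect_lte(abs(which.max(avg["O1", ]) - 125), 1)
  nonavg <- average_segments(segs, "non_stimulus")
  expect_lt(max(abs(nonavg["O1", ]), na.rm = TRUE),
            max(avg["O1", ]) / 3)
})

test_that("segment sets round-trip through the directory format", {
  rec <- toy_recording(n_channels = 2, n_samples = 1000, seed = 5)
  segs <- extract_segments(rec, make_schedule(2.2))
  dir <- tempfile()
  write_segment_set(segs, dir)
  back <- read_segment_set(dir)
  expect_equal(back$info, segs$info, tolerance = 1e-12)
  expect_equal(back$segments, segs$segments, tolerance = 1e-12)
  expect_equal(back$channel_labels, segs$channel_labels)
})
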