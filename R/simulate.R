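#' Simulation configuration for flash-evoked EEG
#'
#' Bundles everything needed to generate a ground-truthed synthetic
#' microperimetry trial: acquisition parameters (250 Hz, 8 occipito-parietal
#' channels), the stimulus program (200-ms flashes separated by 2-3 s,
#' intensity on the device dB attenuation scale), the evoked-response model
#' (Gaussian-windowed deflections with occipital-dominant per-channel gains),
#' the background/noise model (1/f activity, amplitude-modulated alpha,
#' common-mode blink transients, channel-local muscle bursts), and the
#' synchronization-error bound of the offline video-based event annotation.
#'
#' @param duration Recording length in seconds.
#' @param n_stimuli Number of flash presentations.
#' @param sampling_rate Sampling rate in Hz. Default 250.
#' @param channel_labels Ordered channel names. Default the 8-channel
#'   parieto-occipital montage P3, P4, PO3, PO4, POz, O1, O2, Oz.
#' @param stimulus_duration Flash duration in seconds. Default 0.2.
#' @param isi_range Length-2 numeric, bounds in seconds of the uniform
#'   inter-stimulus gap (offset to next onset). Default `c(2, 3)`.
#' @param intensity_db Stimulus attenuation in dB, scalar (recycled) or one
#'   value per stimulus. Default 4 (high-intensity condition; 16 dB is the
#'   low-intensity condition).
#' @param vep_params List with numeric vectors `latency` (s from flash onset),
#'   `amplitude` (uV, sign = deflection polarity) and `width` (Gaussian SD, s)
#'   of the evoked components. Defaults to an N75/P100/N135 triphasic response
#'   (-2, +5, -3 uV; widths 20/25/30 ms).
#' @param topography Named per-channel gain in `[0, 1]` multiplying the evoked
#'   template; occipital-dominant by default.
#' @param noise_params List controlling the background: `pink_sd` (uV, total
#'   SD of the 1/f process), `pink_exponent` (spectral slope), `alpha_sd` (uV),
#'   `alpha_freq` (Hz), `blink_rate` (events/s, common-mode biphasic
#'   transients), `blink_amp` (uV), `muscle_rate` (bursts/s/channel),
#'   `muscle_amp` (uV).
#' @param amplitude_exponent Exponent of the compressive luminance-to-amplitude
#'   power law (see [amplitude_scale()]). Default 0.3.
#' @param max_sync_error Bound in seconds of the uniform timestamp error of the
#'   offline synchronization. Default 0.25.
#' @param rng_seed Integer seed controlling every random draw of the
#'   generator.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(duration,
                       n_stimuli,
                       sampling_rate = 250,
                       channel_labels = c("P3", "P4", "PO3", "PO4", "POz",
                                          "O1", "O2", "Oz"),
                       stimulus_duration = 0.2,
                       isi_range = c(2, 3),
                       intensity_db = 4,
                       vep_params = list(latency = c(0.075, 0.100, 0.135),
                                         amplitude = c(-2, 5, -3),
                                         width = c(0.020, 0.025, 0.030)),
                       topography = c(P3 = 0.2, P4 = 0.2, PO3 = 0.35,
                                      PO4 = 0.35, POz = 0.4, O1 = 1, O2 = 1,
                                      Oz = 0.8),
                       noise_params = list(pink_sd = 1.5, pink_exponent = 1,
                                           alpha_sd = 1.0, alpha_freq = 10,
                                           blink_rate = 0.1, blink_amp = 25,
                                           muscle_rate = 0.05, muscle_amp = 4),
                       amplitude_exponent = 0.3,
                       max_sync_error = 0.25,
                       rng_seed = 1L) {
  cfg <- list(duration = duration, n_stimuli = n_stimuli,
              sampling_rate = sampling_rate,
              channel_labels = as.character(channel_labels),
              stimulus_duration = stimulus_duration,
              isi_range = as.numeric(isi_range),
              intensity_db = intensity_db, vep_params = vep_params,
              topography = topography, noise_params = noise_params,
              amplitude_exponent = amplitude_exponent,
              max_sync_error = max_sync_error,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  assert_scalar_number(cfg$sampling_rate, "sampling_rate")
  if (cfg$sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  assert_scalar_number(cfg$stimulus_duration, "stimulus_duration")
  if (cfg$stimulus_duration <= 0)
    stop("stimulus_duration must be > 0", call. = FALSE)
  if (length(cfg$isi_range) != 2L || cfg$isi_range[1] > cfg$isi_range[2] ||
      any(cfg$isi_range < 0))
    stop("isi_range must be a nonnegative pair with low <= high",
         call. = FALSE)
  assert_scalar_number(cfg$duration, "duration", lower = 0)
  assert_scalar_number(cfg$n_stimuli, "n_stimuli", lower = 0)
  assert_scalar_number(cfg$max_sync_error, "max_sync_error", lower = 0)
  if (!length(cfg$channel_labels) || anyDuplicated(cfg$channel_labels))
    stop("channel_labels must be non-empty and unique", call. = FALSE)
  topo <- cfg$topography
  if (is.null(names(topo)) ||
      !all(cfg$channel_labels %in% names(topo)))
    stop("topography must be named with a gain for every channel",
         call. = FALSE)
  if (any(topo < 0)) stop("topography gains must be nonnegative", call. = FALSE)
  occ <- grep("^(O|PO)", cfg$channel_labels, value = TRUE)
  if (length(occ) && all(topo[occ] <= 0))
    stop("at least one occipital/parieto-occipital gain must be > 0",
         call. = FALSE)
  n_int <- length(cfg$intensity_db)
  if (!(n_int == 1L || n_int == cfg$n_stimuli))
    stop("intensity_db must be scalar or one value per stimulus",
         call. = FALSE)
  if (any(cfg$intensity_db < 0))
    stop("intensity_db must be >= 0", call. = FALSE)
  vp <- cfg$vep_params
  if (!all(c("latency", "amplitude", "width") %in% names(vp)) ||
      length(unique(lengths(vp[c("latency", "amplitude", "width")]))) != 1L)
    stop("vep_params needs equal-length latency, amplitude, width",
         call. = FALSE)
  if (any(vp$latency >= 0.6))
    stop("vep component latencies must be < 0.6 s", call. = FALSE)
  need <- cfg$n_stimuli * (cfg$stimulus_duration + cfg$isi_range[1])
  if (cfg$duration < need)
    stop(sprintf(paste0("duration (%g s) too short for %d stimuli at minimum ",
                        "spacing (need >= %g s)"),
         cfg$duration, cfg$n_stimuli, need), call. = FALSE)
  cfg
}

#' High signal-to-noise preset of the simulator
#'
#' Same acquisition conditions as [sim_config()] but with evoked-component
#' amplitudes scaled so the P100 peak is at least five times the total
#' background SD -- the regime in which single-segment detectability should be
#' close to ceiling. Used by the parameter-recovery experiments.
#'
#' @inheritParams sim_config
#' @param ... Passed on to [sim_config()].
#' @export
sim_config_high_snr <- function(duration, n_stimuli, ...) {
  cfg <- sim_config(duration = duration, n_stimuli = n_stimuli, ...)
  noise_sd <- sqrt(cfg$noise_params$pink_sd^2 + cfg$noise_params$alpha_sd^2)
  peak <- max(abs(cfg$vep_params$amplitude))
  target <- 5 * noise_sd / amplitude_scale(max(cfg$intensity_db),
                                           cfg$amplitude_exponent)
  if (peak < target)
    cfg$vep_params$amplitude <- cfg$vep_params$amplitude * target / peak
  cfg
}

validate_schedule <- function(schedule) {
  need <- c("true_onset", "true_offset", "logged_offset", "intensity_db")
  if (!is.data.frame(schedule) || !all(need %in% names(schedule)))
    stop("schedule must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (nrow(schedule) > 1L) {
    if (is.unsorted(schedule$true_onset, strictly = TRUE))
      stop("events must be strictly ordered by onset", call. = FALSE)
    if (any(schedule$true_onset[-1L] <
            schedule$true_offset[-nrow(schedule)]))
      stop("events must not overlap", call. = FALSE)
  }
  invisible(schedule)
}

#' Generate a stimulus presentation schedule
#'
#' Draws a sequence of flash events: each gap (including the lead-in before
#' the first flash) is uniform on `isi_range`, truncated from above where
#' necessary so that the remaining events are always guaranteed to fit within
#' `duration` at the minimum spacing. `logged_offset` starts equal to
#' `true_offset`; apply [apply_timing_jitter()] to emulate offline
#' synchronization error.
#'
#' @param config A [sim_config()].
#' @param rng_seed Optional seed overriding `config$rng_seed`.
#' @return Data frame with one row per stimulus: `true_onset`, `true_offset`,
#'   `logged_offset` (seconds) and `intensity_db`.
#' @export
generate_stimulus_schedule <- function(config, rng_seed = NULL) {
  config <- validate_sim_config(config)
  n <- as.integer(config$n_stimuli)
  if (n == 0L)
    return(data.frame(true_onset = numeric(0), true_offset = numeric(0),
                      logged_offset = numeric(0), intensity_db = numeric(0)))
  sd_ <- config$stimulus_duration
  lo <- config$isi_range[1]; hi <- config$isi_range[2]
  seed <- rng_seed %||% child_seed(config$rng_seed, 1L)
  onsets <- numeric(n)
  with_seed(seed, {
    t <- 0
    for (i in seq_len(n)) {
      remaining <- (n - i) * (sd_ + lo)  # events after this one, min spacing
      slack <- config$duration - t - remaining - sd_
      gap <- stats::runif(1, lo, min(hi, max(lo, slack)))
      onsets[i] <- t + gap
      t <- onsets[i] + sd_
    }
  })
  intensity <- rep_len(config$intensity_db, n)
  out <- data.frame(true_onset = onsets, true_offset = onsets + sd_,
                    logged_offset = onsets + sd_, intensity_db = intensity)
  if (utils::tail(out$true_offset, 1) > config$duration + 1e-9)
    stop("duration too short to place all events", call. = FALSE)
  validate_schedule(out)
  out
}

#' Apply synchronization timing error to logged event timestamps
#'
#' Offline video-based annotation observes stimulus offsets late: the logged
#' offset is modeled as the true offset plus a uniform error on
#' `[0, max_error]`. A symmetric variant (uniform on `[-max_error, max_error]`)
#' is available for sensitivity analyses. True event fields are never touched.
#'
#' @param schedule Stimulus schedule data frame.
#' @param max_error Error bound in seconds (`>= 0`).
#' @param rng_seed Optional integer seed.
#' @param symmetric If `TRUE`, draw errors uniform on
#'   `[-max_error, max_error]` instead of one-sided.
#' @return The schedule with `logged_offset` perturbed.
#' @export
apply_timing_jitter <- function(schedule, max_error, rng_seed = NULL,
                                symmetric = FALSE) {
  validate_schedule(schedule)
  assert_scalar_number(max_error, "max_error", lower = 0)
  n <- nrow(schedule)
  err <- with_seed(rng_seed, {
    if (symmetric) stats::runif(n, -max_error, max_error)
    else stats::runif(n, 0, max_error)
  })
  schedule$logged_offset <- schedule$true_offset + err
  schedule
}

#' Synthesize the single-channel evoked-response template
#'
#' The flash-evoked response is modeled as a sum of Gaussian-windowed
#' deflections, `sum_k a_k * exp(-(t - l_k)^2 / (2 w_k^2))`, with default
#' components N75 (-2 uV), P100 (+5 uV) and N135 (-3 uV) so the whole response
#' is supported well within 300 ms of flash onset. The returned waveform is
#' truncated at the last component's latency plus four widths (capped at
#' 600 ms).
#'
#' @param vep_params List with `latency`, `amplitude`, `width` vectors (see
#'   [sim_config()]).
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric waveform in uV sampled at `sampling_rate`, time-locked to
#'   flash onset at its first sample.
#' @export
synthesize_vep_template <- function(vep_params, sampling_rate) {
  stopifnot(all(c("latency", "amplitude", "width") %in% names(vep_params)))
  if (any(vep_params$latency >= 0.6))
    stop("component latencies must be < 0.6 s", call. = FALSE)
  t_end <- min(0.6, max(vep_params$latency + 4 * vep_params$width))
  n <- time_to_sample(t_end, sampling_rate) + 1L
  t <- (seq_len(n) - 1L) / sampling_rate
  w <- numeric(n)
  for (k in seq_along(vep_params$latency)) {
    w <- w + vep_params$amplitude[k] *
      exp(-(t - vep_params$latency[k])^2 / (2 * vep_params$width[k]^2))
  }
  w
}

# --- background/noise components ------------------------------------------

# 1/f ("pink") process by spectral shaping of white Gaussian noise, rescaled
# to the requested standard deviation.
synth_pink_noise <- function(n, sd_target, exponent) {
  if (sd_target <= 0) return(numeric(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))  # DC handled as lowest bin to avoid division by 0
  f <- pmin(f, n - f + 1)    # two-sided frequency magnitude
  shape <- f^(-exponent / 2)
  shape[1] <- 0              # remove DC
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  y * sd_target / stats::sd(y)
}

# Amplitude-modulated alpha rhythm: a sinusoid at alpha_freq whose envelope
# waxes and wanes slowly (0.2 Hz), normalized to the requested SD.
synth_alpha <- function(n, fs, sd_target, freq) {
  if (sd_target <= 0) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  phase <- stats::runif(1, 0, 2 * pi)
  env_phase <- stats::runif(1, 0, 2 * pi)
  env <- 1 + 0.8 * sin(2 * pi * 0.2 * t + env_phase)
  y <- env * sin(2 * pi * freq * t + phase)
  y * sd_target / stats::sd(y)
}

# Blink-like artifact: slow biphasic transient, identical on every channel
# (common mode); common median re-referencing should reject it.
synth_blinks <- function(n, fs, rate, amp, duration_s) {
  y <- numeric(n)
  if (rate <= 0 || amp <= 0) return(y)
  k <- stats::rpois(1, rate * duration_s)
  if (k == 0) return(y)
  centers <- stats::runif(k, 0, duration_s)
  t <- (seq_len(n) - 1) / fs
  for (c0 in centers) {
    y <- y + amp * (exp(-(t - c0)^2 / (2 * 0.08^2)) -
                    0.6 * exp(-(t - c0 - 0.15)^2 / (2 * 0.12^2)))
  }
  y
}

# Channel-local muscle burst: 300-ms Gaussian-enveloped high-frequency noise.
synth_muscle <- function(n, fs, rate, amp, duration_s) {
  y <- numeric(n)
  if (rate <= 0 || amp <= 0) return(y)
  k <- stats::rpois(1, rate * duration_s)
  if (k == 0) return(y)
  centers <- stats::runif(k, 0, duration_s)
  t <- (seq_len(n) - 1) / fs
  for (c0 in centers) {
    env <- exp(-(t - c0)^2 / (2 * 0.075^2))
    y <- y + amp * env * stats::rnorm(n)
  }
  y
}

#' Simulate a flash-evoked EEG recording
#'
#' Builds `background + injected responses`: per-channel 1/f noise and alpha
#' activity, common-mode blink transients, channel-local muscle bursts, and --
#' at each event's **true** onset -- the evoked template scaled by the
#' channel's topography gain and by the compressive intensity-to-amplitude map
#' (see [amplitude_scale()]). All random draws are governed by
#' `config$rng_seed`, and the noise stream does not depend on the schedule or
#' the evoked-response parameters, so a run with zero amplitudes is an exact
#' noise-only reference for superposition audits.
#'
#' @param schedule Stimulus schedule (see [generate_stimulus_schedule()]).
#' @param config A [sim_config()].
#' @return An [new_recording()] object, channels x samples in uV.
#' @export
simulate_recording <- function(schedule, config) {
  config <- validate_sim_config(config)
  validate_schedule(schedule)
  fs <- config$sampling_rate
  n <- time_to_sample(config$duration, fs)
  labels <- config$channel_labels
  nch <- length(labels)
  if (nrow(schedule) &&
      utils::tail(schedule$true_offset, 1) > config$duration + 1e-9)
    stop("schedule extends beyond the configured duration", call. = FALSE)

  np <- config$noise_params
  data <- matrix(0, nrow = nch, ncol = n, dimnames = list(labels, NULL))
  with_seed(child_seed(config$rng_seed, 3L), {
    blink <- synth_blinks(n, fs, np$blink_rate, np$blink_amp, config$duration)
    for (i in seq_len(nch)) {
      data[i, ] <- synth_pink_noise(n, np$pink_sd, np$pink_exponent) +
        synth_alpha(n, fs, np$alpha_sd, np$alpha_freq) +
        blink +
        synth_muscle(n, fs, np$muscle_rate, np$muscle_amp, config$duration)
    }
  })

  if (nrow(schedule)) {
    template <- synthesize_vep_template(config$vep_params, fs)
    gains <- config$topography[labels]
    for (e in seq_len(nrow(schedule))) {
      i0 <- time_to_sample(schedule$true_onset[e], fs) + 1L
      idx <- i0:min(n, i0 + length(template) - 1L)
      if (!length(idx) || idx[1] > n) next
      scaled <- template[seq_along(idx)] *
        amplitude_scale(schedule$intensity_db[e], config$amplitude_exponent)
      data[, idx] <- data[, idx] + outer(unname(gains), scaled)
    }
  }
  new_recording(data, fs, labels)
}

#' Read and write simulation configurations as YAML
#'
#' @param config A [sim_config()].
#' @param path File path.
#' @export
write_sim_config_yaml <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  out <- unclass(config)
  out$topography <- as.list(config$topography)  # keep channel names in YAML
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_sim_config_yaml
#' @export
read_sim_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$topography <- unlist(raw$topography)
  do.call(sim_config, raw)
}
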