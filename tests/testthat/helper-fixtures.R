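# Shared fixtures and independent oracles. Everything here is deliberately
# written without calling the code paths it is used to check.

# A small deterministic multichannel recording of sinusoids plus noise.
toy_recording <- function(n_channels = 4, n_samples = 500, fs = 250,
                          seed = 1) {
  set.seed(seed)
  data <- t(sapply(seq_len(n_channels), function(i) {
    sin(2 * pi * (4 + i) * (seq_len(n_samples) - 1) / fs) +
      0.3 * rnorm(n_samples)
  }))
  new_recording(data, fs, paste0("ch", seq_len(n_channels)))
}

# Build a segment_set directly from a list of channels x window matrices,
# bypassing extract_segments, for classifier/splitting tests.
make_segment_set <- function(mats, labels, fs = 250,
                             channels = rownames(mats[[1]])) {
  ws <- ncol(mats[[1]])
  info <- data.frame(
    segment_id = sprintf("seg%04d", seq_along(mats)),
    label = labels, trial_id = "toy",
    start_time = (seq_along(mats) - 1) * ws / fs,
    padded_samples = 0L)
  flashvep:::new_segment_set(mats, info, channels, fs, ws)
}

# Constant-valued sequences: class "stimulus" all +1, "non_stimulus" all -1.
# Linearly separable by design.
separable_segment_set <- function(n_per_class = 8, ws = 150) {
  mats <- c(lapply(seq_len(n_per_class),
                   function(i) matrix(1, 1, ws, dimnames = list("O1", NULL))),
            lapply(seq_len(n_per_class),
                   function(i) matrix(-1, 1, ws,
                                      dimnames = list("O1", NULL))))
  make_segment_set(mats, rep(c("stimulus", "non_stimulus"),
                             each = n_per_class))
}

# Independent brute-force tiler: given recording length (samples), window
# length and the 0-based stimulus windows, marks covered samples one by one
# and walks every uncovered run left to right. Returns the non-stimulus
# chunks as (start, real_len), applying the >= 25%-fill rule to the trailing
# partial chunk of each run.
brute_force_tiling <- function(n, ws, stim_starts, stim_ends,
                               min_fill = 0.25) {
  covered <- rep(FALSE, n)
  for (i in seq_along(stim_starts))
    covered[(stim_starts[i] + 1):stim_ends[i]] <- TRUE
  out <- list()
  s <- 0
  while (s < n) {
    if (covered[s + 1]) { s <- s + 1; next }
    e <- s
    while (e < n && !covered[e + 1]) e <- e + 1
    g <- s
    while (g < e) {
      len <- min(ws, e - g)
      if (len == ws || len >= min_fill * ws)
        out[[length(out) + 1]] <- c(start = g, real_len = len)
      g <- g + ws
    }
    s <- e
  }
  if (length(out)) as.data.frame(do.call(rbind, out))
  else data.frame(start = integer(0), real_len = integer(0))
}

# 0-based stimulus window bounds computed independently of the package.
oracle_stim_windows <- function(logged_offsets, fs, ws) {
  ends <- as.integer(floor(logged_offsets * fs + 0.5))
  data.frame(start = ends - ws, end = ends)
}

# Small training configuration for fast deterministic fits.
quick_train_config <- function(...) {
  train_config(hidden_units = 12L, max_epochs = 30L,
               early_stop_patience = 6L, learning_rate = 3e-3, ...)
}
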