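#' Offset-locked segmentation into labeled 600-ms epochs
#'
#' Cuts a recording into equal-length windows: one *stimulus* segment per
#' event, spanning the `window` seconds ending at the event's logged offset
#' (half-open `[offset - window, offset)` in samples), and the remaining
#' signal tiled left-to-right, gap by gap, into *non-stimulus* windows of the
#' same length. A final partial chunk in a gap is kept zero-padded at its tail
#' provided at least `min_fill` of the window is real signal; shorter slivers
#' are discarded so near-empty padded segments do not inflate the majority
#' class. Events whose window does not fit inside the recording are dropped
#' with a warning; events closer together than `window` are an error.
#'
#' @param recording A preprocessed [new_recording()] object.
#' @param schedule Stimulus schedule data frame; segmentation is keyed to
#'   `logged_offset` (the synchronization-limited timestamps), with
#'   `true_offset` retained in the manifest for diagnostics.
#' @param window Window length in seconds. Default 0.6 (150 samples at
#'   250 Hz).
#' @param min_fill Minimum fraction of real samples for a padded trailing
#'   chunk to be kept. Default 0.25.
#' @param trial_id Identifier stored with every segment.
#' @return A `segment_set`: list of `channels x window_samples` matrices plus
#'   a manifest data frame (`segment_id`, `label`, `trial_id`, `start_time`,
#'   `padded_samples`).
#' @export
extract_segments <- function(recording, schedule, window = 0.6,
                             min_fill = 0.25, trial_id = "trial") {
  stopifnot(inherits(recording, "eeg_recording"))
  validate_schedule(schedule)
  assert_scalar_number(window, "window")
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  fs <- recording$sampling_rate
  ws <- time_to_sample(window, fs)
  n <- n_samples(recording)

  ends <- time_to_sample(schedule$logged_offset, fs)  # 0-based exclusive ends
  starts <- ends - ws
  fits <- starts >= 0L & ends <= n
  if (any(!fits))
    warning(sum(!fits), " event(s) do not fit in the recording and were ",
            "dropped", call. = FALSE)
  keep <- which(fits)
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) > 1L) {
    ord <- order(starts)
    starts <- starts[ord]; ends <- ends[ord]; keep <- keep[ord]
    clash <- which(starts[-1L] < ends[-length(ends)])
    if (length(clash))
      stop("overlapping stimulus windows (offsets closer than the window) ",
           "for events: ",
           paste(sprintf("%d/%d", keep[clash], keep[clash + 1L]),
                 collapse = ", "), call. = FALSE)
  }

  segments <- list()
  info <- list()
  add_segment <- function(s0, real_len, label) {
    seg <- matrix(0, nrow = nrow(recording$data), ncol = ws,
                  dimnames = list(recording$channel_labels, NULL))
    seg[, seq_len(real_len)] <-
      recording$data[, (s0 + 1L):(s0 + real_len), drop = FALSE]
    segments[[length(segments) + 1L]] <<- seg
    info[[length(info) + 1L]] <<- data.frame(
      label = label, trial_id = trial_id, start_time = s0 / fs,
      padded_samples = ws - real_len)
  }

  # Non-stimulus gaps: maximal sample runs outside every stimulus window.
  gap_bounds <- cbind(c(0L, ends), c(starts, n))
  for (g in seq_len(nrow(gap_bounds))) {
    s <- gap_bounds[g, 1L]; e <- gap_bounds[g, 2L]
    while (s < e) {
      real_len <- min(ws, e - s)
      if (real_len == ws || real_len >= min_fill * ws)
        add_segment(s, real_len, "non_stimulus")
      s <- s + ws
    }
  }
  for (i in seq_along(starts)) add_segment(starts[i], ws, "stimulus")

  info <- if (length(info)) do.call(rbind, info) else
    data.frame(label = character(0), trial_id = character(0),
               start_time = numeric(0), padded_samples = integer(0))
  ord <- order(info$start_time)
  info <- info[ord, , drop = FALSE]
  segments <- segments[ord]
  info <- cbind(segment_id = sprintf("%s_seg%04d", trial_id,
                                     seq_len(nrow(info))), info)
  rownames(info) <- NULL
  new_segment_set(segments, info, recording$channel_labels, fs, ws)
}

new_segment_set <- function(segments, info, channel_labels, sampling_rate,
                            window_samples) {
  structure(
    list(segments = segments, info = info, channel_labels = channel_labels,
         sampling_rate = sampling_rate, window_samples = window_samples),
    class = "segment_set"
  )
}

#' @export
print.segment_set <- function(x, ...) {
  counts <- class_counts(x)
  cat(sprintf(paste0("<segment_set> %d segments of %d samples x %d channels ",
                     "(%d stimulus, %d non-stimulus)\n"),
              length(x$segments), x$window_samples,
              length(x$channel_labels),
              counts[["stimulus"]], counts[["non_stimulus"]]))
  invisible(x)
}

#' Class counts of a segment set
#'
#' @param segment_set A `segment_set`.
#' @return Named integer vector with `stimulus` and `non_stimulus` totals.
#' @export
class_counts <- function(segment_set) {
  stopifnot(inherits(segment_set, "segment_set"))
  c(stimulus = sum(segment_set$info$label == "stimulus"),
    non_stimulus = sum(segment_set$info$label == "non_stimulus"))
}

# Subset a segment_set by row indices of the manifest.
subset_segments <- function(segment_set, idx) {
  new_segment_set(segment_set$segments[idx],
                  segment_set$info[idx, , drop = FALSE],
                  segment_set$channel_labels, segment_set$sampling_rate,
                  segment_set$window_samples)
}

#' Subset every segment to an electrode montage
#'
#' @param segment_set A `segment_set`.
#' @param channels Channel labels to keep, in the requested order.
#' @return A `segment_set` restricted to `channels`.
#' @export
select_segment_channels <- function(segment_set, channels) {
  stopifnot(inherits(segment_set, "segment_set"))
  channels <- as.character(channels)
  missing <- setdiff(channels, segment_set$channel_labels)
  if (length(missing))
    stop("channels not present in segments: ",
         paste(missing, collapse = ", "), call. = FALSE)
  segs <- lapply(segment_set$segments,
                 function(s) s[channels, , drop = FALSE])
  new_segment_set(segs, segment_set$info, channels,
                  segment_set$sampling_rate, segment_set$window_samples)
}

#' Average segments of one class
#'
#' Pointwise mean waveform across all segments of the requested label, used to
#' inspect whether a distinguishable evoked pattern survives averaging.
#' Zero-padded tail samples are excluded via per-point counts rather than
#' averaged as real zeros; a time point padded in every segment is `NA`.
#'
#' @param segment_set A `segment_set`.
#' @param label `"stimulus"` or `"non_stimulus"`.
#' @return A `channels x window_samples` matrix of means.
#' @export
average_segments <- function(segment_set, label = c("stimulus",
                                                    "non_stimulus")) {
  stopifnot(inherits(segment_set, "segment_set"))
  label <- match.arg(label)
  idx <- which(segment_set$info$label == label)
  if (!length(idx))
    stop("no segments with label '", label, "'", call. = FALSE)
  ws <- segment_set$window_samples
  nch <- length(segment_set$channel_labels)
  acc <- matrix(0, nch, ws)
  counts <- numeric(ws)
  for (i in idx) {
    real <- ws - segment_set$info$padded_samples[i]
    acc[, seq_len(real)] <- acc[, seq_len(real)] +
      segment_set$segments[[i]][, seq_len(real), drop = FALSE]
    counts[seq_len(real)] <- counts[seq_len(real)] + 1
  }
  out <- sweep(acc, 2L, counts, "/")  # columns with count 0 become NaN
  out[, counts == 0] <- NA_real_
  rownames(out) <- segment_set$channel_labels
  out
}

#' Serialize a segment set to a directory
#'
#' Writes one CSV matrix per segment plus a `manifest.tsv` with columns
#' `segment_id`, `label`, `trial_id`, `start_time`, `padded_samples`.
#'
#' @param segment_set A `segment_set`.
#' @param dir Output directory (created if needed).
#' @export
write_segment_set <- function(segment_set, dir) {
  stopifnot(inherits(segment_set, "segment_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(segment_set$info, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(channel_labels = segment_set$channel_labels,
               sampling_rate = segment_set$sampling_rate,
               window_samples = segment_set$window_samples)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  for (i in seq_along(segment_set$segments)) {
    utils::write.csv(t(segment_set$segments[[i]]),
                     file.path(dir, paste0(segment_set$info$segment_id[i],
                                           ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_segment_set
#' @export
read_segment_set <- function(dir) {
  info <- utils::read.delim(file.path(dir, "manifest.tsv"),
                            colClasses = c(segment_id = "character",
                                           label = "character",
                                           trial_id = "character"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  segs <- lapply(info$segment_id, function(id) {
    m <- t(unname(as.matrix(utils::read.csv(file.path(dir,
                                                      paste0(id, ".csv")),
                                            check.names = FALSE))))
    rownames(m) <- meta$channel_labels
    m
  })
  new_segment_set(segs, info, meta$channel_labels, meta$sampling_rate,
                  meta$window_samples)
}
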