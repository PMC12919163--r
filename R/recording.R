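#' Multichannel EEG recording container
#'
#' A lightweight container for a continuous multichannel EEG recording:
#' a channels-by-samples numeric matrix in microvolts, the sampling rate in
#' Hz, and ordered channel labels.
#'
#' @param data Numeric matrix, channels in rows, samples in columns (uV).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique channel names, one per row
#'   of `data`.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, sampling_rate, channel_labels) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)", call. = FALSE)
  assert_scalar_number(sampling_rate, "sampling_rate")
  if (sampling_rate <= 0) stop("`sampling_rate` must be > 0", call. = FALSE)
  channel_labels <- as.character(channel_labels)
  if (nrow(data) != length(channel_labels))
    stop("`data` must have exactly length(channel_labels) rows", call. = FALSE)
  if (anyDuplicated(channel_labels))
    stop("`channel_labels` must be unique", call. = FALSE)
  if (!all(is.finite(data)))
    stop("recording values must all be finite", call. = FALSE)
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = channel_labels),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

recording_duration <- function(rec) ncol(rec$data) / rec$sampling_rate

#' Subset a recording to an electrode montage
#'
#' @param recording An `eeg_recording`.
#' @param channels Channel labels to keep, in the requested order.
#' @return An `eeg_recording` containing only the requested channels.
#' @export
select_channels <- function(recording, channels) {
  stopifnot(inherits(recording, "eeg_recording"))
  channels <- as.character(channels)
  missing <- setdiff(channels, recording$channel_labels)
  if (length(missing))
    stop("channels not present in recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  new_recording(recording$data[channels, , drop = FALSE],
                recording$sampling_rate, channels)
}

#' Read and write recordings as labeled CSV
#'
#' Recordings are serialized as plain CSV with one column per channel (header
#' row of channel labels) and one row per sample. The sampling rate is not
#' stored in the file and must be supplied on read.
#'
#' @param recording An `eeg_recording`.
#' @param path File path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an `eeg_recording`.
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  df <- as.data.frame(t(recording$data))
  names(df) <- recording$channel_labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @param sampling_rate Sampling rate in Hz of the stored recording.
#' @export
read_recording_csv <- function(path, sampling_rate) {
  df <- utils::read.csv(path, check.names = FALSE)
  new_recording(t(as.matrix(df)), sampling_rate, names(df))
}

#' Read and write stimulus event schedules as TSV
#'
#' Event tables carry `true_onset`, `true_offset`, `logged_offset` (seconds)
#' and `intensity_db` (dB) columns.
#'
#' @param schedule A stimulus schedule data frame (see
#'   [generate_stimulus_schedule()]).
#' @param path File path.
#' @export
write_events_tsv <- function(schedule, path) {
  validate_schedule(schedule)
  utils::write.table(
    schedule[, c("true_onset", "true_offset", "logged_offset", "intensity_db")],
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- utils::read.delim(path)
  validate_schedule(df)
  df
}
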