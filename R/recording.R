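#' Construct a multichannel EEG recording
#'
#' A lightweight container for a channels-by-time amplitude matrix, its
#' sampling rate and per-sample artifact masks. Masks never modify sample
#' values: all downstream exclusion (spectral windows, phase-locking sums)
#' is driven by the masks.
#'
#' @param samples numeric matrix, channels in rows, time in columns.
#'   Amplitudes are in the recording's native units.
#' @param fs sampling rate in Hz (default 256).
#' @param channel_names character vector of unique channel labels, one per
#'   row of `samples`. Defaults to the canonical 20-channel montage when the
#'   row count matches.
#' @param artifact_mask optional logical matrix, same shape as `samples`,
#'   marking contaminated samples.
#' @param blink_mask optional logical matrix marking blink-contaminated
#'   samples (kept separately because the blink rate feature counts only
#'   these).
#' @return an object of class `eeg_recording`.
#' @examples
#' x <- matrix(rnorm(20 * 512), nrow = 20)
#' rec <- eeg_recording(x, fs = 256)
#' rec
#' @export
eeg_recording <- function(samples, fs = 256, channel_names = NULL,
                          artifact_mask = NULL, blink_mask = NULL) {
  if (!is.matrix(samples) || !is.numeric(samples) || ncol(samples) < 1 ||
      nrow(samples) < 1) {
    abort("`samples` must be a non-empty numeric channels x time matrix")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    abort("`fs` must be a single positive number (Hz)")
  }
  if (is.null(channel_names)) {
    channel_names <- if (nrow(samples) == 20) eeg_channels() else
      paste0("ch", seq_len(nrow(samples)))
  }
  if (length(channel_names) != nrow(samples) ||
      anyDuplicated(channel_names)) {
    abort("`channel_names` must be unique, one per channel row")
  }
  check_mask <- function(m, what) {
    if (is.null(m)) m <- matrix(FALSE, nrow(samples), ncol(samples))
    if (!is.logical(m) || !identical(dim(m), dim(samples))) {
      abort(paste0("`", what, "` must be a logical matrix shaped like `samples`"))
    }
    m
  }
  structure(
    list(samples = samples, fs = fs, channel_names = channel_names,
         artifact_mask = check_mask(artifact_mask, "artifact_mask"),
         blink_mask = check_mask(blink_mask, "blink_mask")),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  cat(sprintf("  channels: %s\n", paste(head(x$channel_names, 8),
                                        collapse = ", ")))
  cat(sprintf("  masked: %.2f%% artifact, %.2f%% blink\n",
              100 * mean(x$artifact_mask), 100 * mean(x$blink_mask)))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$samples)

n_samples <- function(rec) ncol(rec$samples)

#' Number of samples and duration of a recording
#'
#' @param rec an [eeg_recording()].
#' @return `recording_duration()` returns the duration in seconds
#'   (the completion-time feature CT = N / fs).
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$samples) / rec$fs
}

channel_index <- function(rec, channels) {
  idx <- match(channels, rec$channel_names)
  if (anyNA(idx)) {
    abort(paste0("channel(s) missing from recording: ",
                 paste(channels[is.na(idx)], collapse = ", ")))
  }
  idx
}

#' Read a recording from a delimited text table
#'
#' Expects channels as columns with a header row of channel labels; one
#' sample per row. The sampling rate is not stored in the file and must be
#' supplied.
#'
#' @param path file path of a comma- or whitespace-delimited numeric table.
#' @param fs sampling rate in Hz.
#' @param sep field separator (default `","`).
#' @return an [eeg_recording()].
#' @export
read_eeg_table <- function(path, fs = 256, sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  if (ncol(tab) < 1 || nrow(tab) < 1) abort("empty EEG table")
  eeg_recording(t(as.matrix(tab)), fs = fs, channel_names = colnames(tab))
}

#' Write a recording to a delimited text table
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_eeg_table <- function(rec, path, sep = ",") {
  stopifnot(inherits(rec, "eeg_recording"))
  tab <- as.data.frame(t(rec$samples))
  colnames(tab) <- rec$channel_names
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Combined artifact mask of a recording
#'
#' Union of the spike/saturation artifact mask and the blink mask.
#'
#' @param rec an [eeg_recording()].
#' @return logical channels x time matrix.
#' @export
combined_mask <- function(rec) {
  rec$artifact_mask | rec$blink_mask
}
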