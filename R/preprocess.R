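#' Detect spike and saturation artifacts
#'
#' Scans each channel for contiguous runs of samples whose absolute
#' amplitude exceeds `amp_threshold`. Runs whose length is in `run_lengths`
#' are marked; runs longer than the largest listed length are also marked
#' (a conservative superset rule, since long saturations are at least as
#' contaminated as short spikes). Sample values are never modified.
#'
#' @param rec an [eeg_recording()].
#' @param run_lengths integer vector of spike lengths to flag
#'   (default `c(3, 5, 7)`).
#' @param amp_threshold absolute amplitude threshold in the recording's
#'   native units (default 40).
#' @param mask_long_runs logical; also mask supra-threshold runs longer
#'   than `max(run_lengths)` (default `TRUE`).
#' @return logical channels x time mask, `TRUE` on artifact samples.
#' @examples
#' rec <- eeg_recording(matrix(0, 1, 100), channel_names = "Cz")
#' rec$samples[1, 11:15] <- 50
#' which(detect_spike_artifacts(rec)[1, ])
#' @export
detect_spike_artifacts <- function(rec, run_lengths = c(3, 5, 7),
                                   amp_threshold = 40,
                                   mask_long_runs = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (ncol(rec$samples) == 0) abort("empty recording")
  mask <- matrix(FALSE, nrow(rec$samples), ncol(rec$samples))
  for (ch in seq_len(nrow(rec$samples))) {
    over <- abs(rec$samples[ch, ]) > amp_threshold
    if (!any(over)) next
    r <- rle(over)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    hit <- r$values & (r$lengths %in% run_lengths |
                         (mask_long_runs & r$lengths > max(run_lengths)))
    for (i in which(hit)) mask[ch, starts[i]:ends[i]] <- TRUE
  }
  mask
}

butter_filtfilt <- function(x, filt) {
  as.numeric(signal::filtfilt(filt, x))
}

#' Apply a notch (band-stop) filter
#'
#' Removes narrow-band line noise (60 Hz mains by default) with a
#' zero-phase second-order Butterworth band-stop filter applied
#' forward-backward, so downstream phase estimates are not biased.
#'
#' @param rec an [eeg_recording()].
#' @param freq notch center frequency in Hz; must be below Nyquist.
#' @param width half-width of the stop band in Hz (default 2).
#' @return a filtered [eeg_recording()] (masks carried over unchanged).
#' @export
apply_notch <- function(rec, freq = 60, width = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (freq <= 0 || freq >= nyq) abort("notch frequency must be in (0, fs/2)")
  w <- c(max(freq - width, 0.01), min(freq + width, nyq * 0.999)) / nyq
  filt <- signal::butter(2, w, type = "stop")
  rec$samples <- t(apply(rec$samples, 1, butter_filtfilt, filt = filt))
  rec
}

#' Apply a band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass. Used both for the
#' broad 0.5--128 Hz analysis band and per-band (theta/alpha/beta/gamma)
#' ahead of phase extraction. When `hi` reaches Nyquist the filter
#' degenerates to a high-pass at `lo`.
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi band edges in Hz; `0 < lo < hi <= fs/2`.
#' @param order Butterworth order per pass (default 2; the effective order
#'   doubles under forward-backward application).
#' @return a filtered [eeg_recording()].
#' @export
apply_bandpass <- function(rec, lo, hi, order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(lo > 0 && lo < hi)) abort("need 0 < lo < hi")
  if (hi > nyq) abort("upper band edge exceeds Nyquist frequency")
  filt <- if (hi >= nyq * 0.995) {
    signal::butter(order, lo / nyq, type = "high")
  } else {
    signal::butter(order, c(lo, hi) / nyq, type = "pass")
  }
  rec$samples <- t(apply(rec$samples, 1, butter_filtfilt, filt = filt))
  rec
}

#' Detect eye-blink artifacts on frontal channels
#'
#' A threshold detector: a sample is blink-contaminated when the 0.5--4 Hz
#' band-passed frontal signal exceeds `k` times that channel's median
#' absolute deviation for at least `min_ms` milliseconds. The mask of a
#' frontal channel is shared across all channels of the recording, since a
#' blink contaminates the whole scalp topography at those instants.
#'
#' @param rec an [eeg_recording()].
#' @param frontal_channels channels scanned for blink deflections
#'   (default Fp1, Fp2, F3, F4; missing ones among these are ignored as
#'   long as at least one is present).
#' @param k MAD multiplier (default 6).
#' @param min_ms minimum deflection duration in ms (default 50).
#' @return logical channels x time mask.
#' @export
detect_blinks <- function(rec, frontal_channels = c("Fp1", "Fp2", "F3", "F4"),
                          k = 6, min_ms = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  present <- intersect(frontal_channels, rec$channel_names)
  if (length(present) == 0) abort("no frontal channels present")
  idx <- channel_index(rec, present)
  low <- apply_bandpass(rec, 0.5, 4)
  min_run <- max(1L, ceiling(min_ms / 1000 * rec$fs))
  hit <- rep(FALSE, ncol(rec$samples))
  for (ch in idx) {
    x <- low$samples[ch, ]
    s <- stats::mad(x)
    if (s == 0) next
    over <- abs(x) > k * s
    r <- rle(over)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values & r$lengths >= min_run)) {
      hit[starts[i]:ends[i]] <- TRUE
    }
  }
  matrix(hit, nrow = nrow(rec$samples), ncol = ncol(rec$samples),
         byrow = TRUE)
}

#' Run the standard artifact-masking and filtering chain
#'
#' Convenience wrapper: spike detection, blink detection, 60 Hz notch and
#' broad band-pass, storing the masks on the returned recording. Masks are
#' computed on the raw signal; filters are then applied to the samples.
#'
#' @param rec an [eeg_recording()].
#' @param notch_hz mains frequency (default 60).
#' @param bandpass numeric length-2, broad analysis band (default
#'   `c(0.5, 128)`, truncated to Nyquist).
#' @param spike_threshold amplitude threshold for spike masking.
#' @param blink_k MAD multiplier for blink masking.
#' @return an [eeg_recording()] with filters applied and masks set.
#' @export
preprocess_recording <- function(rec, notch_hz = 60,
                                 bandpass = c(0.5, 128),
                                 spike_threshold = 40, blink_k = 6) {
  stopifnot(inherits(rec, "eeg_recording"))
  rec$artifact_mask <- detect_spike_artifacts(rec,
                                              amp_threshold = spike_threshold)
  rec$blink_mask <- tryCatch(detect_blinks(rec, k = blink_k),
                             error = function(e) rec$blink_mask)
  rec <- apply_notch(rec, notch_hz)
  hi <- min(bandpass[2], rec$fs / 2)
  apply_bandpass(rec, bandpass[1], hi)
}

#' Remove three-sigma outliers from a numeric series
#'
#' Single-pass rule: the mean and (sample) standard deviation are computed
#' once over the full series, and points farther than `n_sd` standard
#' deviations from the mean are dropped. The rule is deliberately not
#' iterated; survivors keep their original order. A constant series has
#' zero SD and is returned unchanged.
#'
#' @param x numeric vector of length >= 2.
#' @param n_sd SD multiplier (default 3).
#' @return list with `values` (survivors) and `removed` (integer indices
#'   of dropped points).
#' @examples
#' remove_outliers(c(0, 0, 0, 100))   # nothing removed: 100 is < 3 SD here
#' @export
remove_outliers <- function(x, n_sd = 3) {
  if (length(x) < 2) abort("series must have length >= 2")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    return(list(values = x, removed = integer(0)))
  }
  bad <- which(abs(x - mean(x)) > n_sd * s)
  list(values = if (length(bad)) x[-bad] else x, removed = bad)
}
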