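#' Mental load of a cognitive system
#'
#' The mental load of system *i* is the sum over its channels *j* of
#' A(j), the channel's time-averaged total integrated power: the
#' spectrogram is integrated over the full analysis band per window, then
#' averaged over retained windows, then summed over the system's channels.
#'
#' @param psd a [compute_psd()] result.
#' @param system one of `"F"`, `"PF"`, `"C"`, `"T"`, `"Pa"`, `"O"`.
#' @param parcellation a [system_parcellation()] list.
#' @return single numeric mental-load value (power units).
#' @export
mental_load <- function(psd, system, parcellation = system_parcellation()) {
  stopifnot(inherits(psd, "psd_spectrogram"))
  chans <- parcellation[[system]]
  if (is.null(chans)) abort(paste0("unknown system: ", system))
  chans <- intersect(chans, psd$channel_names)
  if (length(chans) == 0) abort(paste0("no channels present for system ", system))
  tot <- band_power(psd)                  # channel x window, NA if rejected
  a <- rowMeans(tot[chans, , drop = FALSE], na.rm = TRUE)
  a[is.nan(a)] <- 0
  sum(a)
}

#' Situation awareness: frontal theta plus gamma power
#'
#' Frontal-average theta-band power plus frontal-average gamma-band power.
#' Each term is the band-integrated PSD averaged first over frontal
#' channels and then over retained windows.
#'
#' @inheritParams mental_load
#' @return single numeric SA value (power units).
#' @export
situation_awareness <- function(psd, parcellation = system_parcellation()) {
  stopifnot(inherits(psd, "psd_spectrogram"))
  chans <- intersect(parcellation$F, psd$channel_names)
  if (length(chans) == 0) abort("no frontal channels present")
  term <- function(b) {
    bd <- eeg_bands(b)
    p <- band_power(psd, bd$lo, bd$hi)[chans, , drop = FALSE]
    m <- mean(colMeans(p), na.rm = TRUE)
    if (is.nan(m)) 0 else m
  }
  term("theta") + term("gamma")
}

#' Blink rate: fraction of blink-contaminated samples
#'
#' BR = N_c / N, where N_c counts time points marked in the blink mask
#' (on any channel) and N is the recording length.
#'
#' @param x an [eeg_recording()] with a blink mask, or a logical mask
#'   (vector over time, or channels x time matrix).
#' @return blink rate in \[0, 1\].
#' @export
blink_rate <- function(x) {
  m <- if (inherits(x, "eeg_recording")) x$blink_mask else x
  if (is.matrix(m)) m <- apply(m, 2, any)
  if (length(m) == 0) abort("empty blink mask")
  mean(m)
}

#' Frontal alpha asymmetry index
#'
#' Quantifies lateralized frontal alpha suppression, a marker of negative
#' affect (right-dominant activation under concern lowers right alpha).
#' Per channel, the alpha-band (8--12 Hz) power is integrated per window;
#' the window series is cleaned by single-pass three-sigma outlier removal
#' (raw extrema are otherwise artifact-dominated); the dynamic range
#' max - min over surviving windows is taken. With
#' L = range(F3) + range(F7) and R = range(F4) + range(F8),
#' AI = (L - R) / (L + R), in \[-1, 1\].
#'
#' @inheritParams mental_load
#' @return single numeric AI value.
#' @export
asymmetry_index <- function(psd) {
  stopifnot(inherits(psd, "psd_spectrogram"))
  need <- c("F3", "F4", "F7", "F8")
  if (!all(need %in% psd$channel_names)) {
    abort("asymmetry index needs channels F3, F4, F7, F8")
  }
  bd <- eeg_bands("alpha")
  p <- band_power(psd, bd$lo, bd$hi)
  rng <- function(ch) {
    v <- p[ch, ]
    v <- v[!is.na(v)]
    if (length(v) < 2) return(0)
    v <- remove_outliers(v)$values
    max(v) - min(v)
  }
  l <- rng("F3") + rng("F7")
  r <- rng("F4") + rng("F8")
  if (l + r == 0) abort("degenerate (flat) input: alpha power has no range")
  (l - r) / (l + r)
}

#' Completion time of a recording
#'
#' CT = N / fs: number of samples divided by the sampling rate.
#'
#' @param rec an [eeg_recording()].
#' @return duration in seconds.
#' @export
completion_time <- function(rec) {
  recording_duration(rec)
}

#' All cognitive features of one recording as a tibble row
#'
#' Computes ML per system, SA, BR, AI and CT from a preprocessed recording
#' and its spectrogram. Mental workload (MW) and engagement (E) come from
#' proprietary baseline-calibrated classifiers and are never computed
#' here; they are accepted as optional pass-through values (range-checked
#' probabilities in \[0, 1\]).
#'
#' @param rec a preprocessed [eeg_recording()] (masks set).
#' @param psd optional precomputed [compute_psd()] result.
#' @param MW,E optional externally supplied workload / engagement
#'   probabilities in \[0, 1\]; `NA` when absent.
#' @return one-row tibble with the 12 canonical cognitive columns.
#' @export
cognitive_features <- function(rec, psd = NULL, MW = NA_real_, E = NA_real_) {
  stopifnot(inherits(rec, "eeg_recording"))
  for (v in c(MW, E)) {
    if (!is.na(v) && (v < 0 || v > 1)) {
      abort("MW and E must be probabilities in [0, 1]")
    }
  }
  if (is.null(psd)) psd <- compute_psd(rec)
  parc <- system_parcellation()
  ml <- vapply(names(parc), function(s) mental_load(psd, s, parc), numeric(1))
  out <- tibble(!!!setNames(as.list(ml), paste0("ML_", names(parc))))
  out$SA <- situation_awareness(psd, parc)
  out$E <- E
  out$BR <- blink_rate(rec)
  out$AI <- asymmetry_index(psd)
  out$CT <- completion_time(rec)
  out$MW <- MW
  out[, cognitive_feature_names()]
}
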