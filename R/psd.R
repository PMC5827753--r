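#' Windowed power spectral density (Kaiser-tapered short-time FFT)
#'
#' Computes a per-channel spectrogram with a moving Kaiser-tapered window
#' (1 s, 50% overlap by default). Windows in which more than `reject_frac`
#' of samples are artifact-masked are dropped; in retained windows the
#' masked samples are linearly interpolated before the FFT so the taper
#' sees a continuous series. Densities are one-sided and normalized so
#' that the integral over frequency of a window's PSD equals the signal
#' variance in that window (up to taper leakage).
#'
#' @param rec an [eeg_recording()]; the union of its artifact and blink
#'   masks drives window rejection.
#' @param window_sec analysis window length in seconds (default 1).
#' @param overlap_frac fractional overlap between consecutive windows
#'   (default 0.5).
#' @param kaiser_beta Kaiser shape parameter (default 8.6, giving
#'   Blackman-like sidelobe suppression).
#' @param reject_frac maximum tolerated masked fraction per window
#'   (default 0.25).
#' @return an object of class `psd_spectrogram`: list with `values`
#'   (channel x window x frequency array, `NA` rows for rejected windows),
#'   `freq` (Hz bin centers), `retained` (channel x window logical),
#'   `fs`, `window_sec`, `overlap_frac` and `channel_names`.
#' @export
compute_psd <- function(rec, window_sec = 1, overlap_frac = 0.5,
                        kaiser_beta = 8.6, reject_frac = 0.25) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap_frac < 0 || overlap_frac >= 1) {
    abort("`overlap_frac` must be in [0, 1)")
  }
  nw <- round(window_sec * rec$fs)
  if (nw < 2) abort("window too short: need window_sec * fs >= 2")
  n <- ncol(rec$samples)
  if (n < nw) abort("recording shorter than one analysis window")
  step <- max(1L, round(nw * (1 - overlap_frac)))
  starts <- seq(1L, n - nw + 1L, by = step)
  taper <- signal::kaiser(nw, kaiser_beta)
  u <- sum(taper^2)                      # taper power for density scaling
  nfreq <- nw %/% 2 + 1
  freq <- (seq_len(nfreq) - 1) * rec$fs / nw
  nch <- nrow(rec$samples)
  vals <- array(NA_real_, dim = c(nch, length(starts), nfreq))
  retained <- matrix(FALSE, nch, length(starts))
  mask <- combined_mask(rec)
  for (ch in seq_len(nch)) {
    x_full <- rec$samples[ch, ]
    m_full <- mask[ch, ]
    for (w in seq_along(starts)) {
      sel <- starts[w]:(starts[w] + nw - 1L)
      m <- m_full[sel]
      if (mean(m) > reject_frac) next
      x <- x_full[sel]
      if (any(m)) {
        if (all(m)) next
        x[m] <- stats::approx(which(!m), x[!m], xout = which(m),
                              rule = 2)$y
      }
      X <- stats::fft(x * taper)[seq_len(nfreq)]
      p <- (Mod(X)^2) / (rec$fs * u)
      # one-sided: double all bins except DC (and Nyquist when nw is even)
      dbl <- rep(2, nfreq); dbl[1] <- 1
      if (nw %% 2 == 0) dbl[nfreq] <- 1
      vals[ch, w, ] <- p * dbl
      retained[ch, w] <- TRUE
    }
  }
  structure(
    list(values = vals, freq = freq, retained = retained, fs = rec$fs,
         window_sec = window_sec, overlap_frac = overlap_frac,
         channel_names = rec$channel_names),
    class = "psd_spectrogram"
  )
}

#' @export
print.psd_spectrogram <- function(x, ...) {
  cat(sprintf(
    "<psd_spectrogram> %d channels x %d windows x %d bins (%.3g-%.4g Hz)\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
    min(x$freq), max(x$freq)))
  cat(sprintf("  retained windows: %.1f%%\n", 100 * mean(x$retained)))
  invisible(x)
}

#' Band-integrated power per channel and window
#'
#' Integrates the PSD over `[lo, hi]` (trapezoid-free bin sum times bin
#' width), returning a channel x window matrix with `NA` for rejected
#' windows.
#'
#' @param psd a [compute_psd()] result.
#' @param lo,hi integration limits in Hz; defaults cover the full axis.
#' @return numeric channel x window matrix of integrated power.
#' @export
band_power <- function(psd, lo = -Inf, hi = Inf) {
  stopifnot(inherits(psd, "psd_spectrogram"))
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= lo & psd$freq <= hi
  if (!any(sel)) abort("no frequency bins inside [lo, hi]")
  out <- apply(psd$values[, , sel, drop = FALSE], c(1, 2),
               function(v) sum(v) * df)
  dimnames(out) <- list(psd$channel_names, NULL)
  out
}
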