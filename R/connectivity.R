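analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else if (n > 1) {
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

wrap_pi <- function(phi) {
  # wrap to (-pi, pi]
  out <- (phi + pi) %% (2 * pi) - pi
  out[out == -pi] <- pi
  out
}

#' Instantaneous band-limited phase of each channel
#'
#' Band-pass filters the recording to the requested band (zero-phase) and
#' takes the analytic-signal phase per channel. This is the standard
#' construction behind the phase-locking value: within a narrow band the
#' analytic phase is the instantaneous oscillation phase.
#'
#' @param rec an [eeg_recording()].
#' @param band a band name (`"theta"`, `"alpha"`, `"beta"`, `"gamma"`) or a
#'   list with `lo`/`hi` in Hz.
#' @return object of class `phase_series`: list with `phi` (channels x
#'   time, radians wrapped to (-pi, pi]), `band`, `channel_names`, `mask`
#'   (the recording's combined artifact mask) and `fs`.
#' @export
instantaneous_phase <- function(rec, band) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (is.character(band)) band <- eeg_bands(band)
  if (band$hi >= rec$fs / 2) abort("band extends beyond Nyquist frequency")
  filt <- apply_bandpass(rec, band$lo, band$hi)
  phi <- t(apply(filt$samples, 1, function(x) Arg(analytic_signal(x))))
  structure(
    list(phi = wrap_pi(phi), band = band,
         channel_names = rec$channel_names,
         mask = combined_mask(rec), fs = rec$fs),
    class = "phase_series"
  )
}

#' Absolute instantaneous phase difference of two phase series
#'
#' The signed difference is wrapped to (-pi, pi] and its absolute value
#' taken, giving a series in \[0, pi\]. This folded series is the quantity
#' the synchronization index conceptually averages; note that because
#' cosine is even, the index computed from signed differences is
#' identical, so the folding is a reporting convention, not a different
#' statistic.
#'
#' @param phix,phiy numeric phase vectors (radians), equal length.
#' @return numeric vector of absolute wrapped differences in \[0, pi\].
#' @examples
#' phase_difference(c(0, pi / 2), c(0, 0))
#' @export
phase_difference <- function(phix, phiy) {
  if (length(phix) != length(phiy)) abort("phase series length mismatch")
  abs(wrap_pi(phix - phiy))
}

#' Phase synchronization index of a phase-difference series
#'
#' Gamma = sqrt((sum cos dphi)^2 + (sum sin dphi)^2) / P over the P
#' retained time points: the resultant length of the unit vectors at the
#' phase differences. Gamma = 1 iff the difference is constant; for
#' incoherent differences it decays like 1/sqrt(P).
#'
#' @param dphi numeric vector of phase differences (radians); masked time
#'   points must already be excluded.
#' @return Gamma in \[0, 1\].
#' @examples
#' phase_sync_index(c(0, pi / 2, pi / 4))
#' @export
phase_sync_index <- function(dphi) {
  p <- length(dphi)
  if (p == 0) abort("no usable time points for synchronization index")
  sqrt(sum(cos(dphi))^2 + sum(sin(dphi))^2) / p
}

#' Per-band phase-synchronization connectivity matrix
#'
#' Computes Gamma for every unordered channel pair from the band-limited
#' analytic phases. A time point is excluded for a pair when it is
#' artifact-masked on either channel; the per-pair retained count P is
#' recorded. The matrix is symmetric with unit diagonal (a channel is
#' perfectly locked to itself by definition).
#'
#' @inheritParams instantaneous_phase
#' @return object of class `connectivity_matrix`: list with `gamma_vals`
#'   (channels x channels), `P` (per-pair retained counts) and `band`.
#' @export
connectivity_matrix <- function(rec, band) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (nrow(rec$samples) < 2) abort("need at least 2 channels")
  ph <- instantaneous_phase(rec, band)
  nch <- nrow(ph$phi)
  g <- diag(1, nch)
  pmat <- matrix(ncol(ph$phi), nch, nch)
  for (i in seq_len(nch - 1)) {
    for (j in (i + 1):nch) {
      ok <- !(ph$mask[i, ] | ph$mask[j, ])
      p <- sum(ok)
      if (p == 0) abort(sprintf("pair %s-%s fully masked",
                                ph$channel_names[i], ph$channel_names[j]))
      d <- ph$phi[i, ok] - ph$phi[j, ok]
      g[i, j] <- g[j, i] <- phase_sync_index(d)
      pmat[i, j] <- pmat[j, i] <- p
    }
  }
  dimnames(g) <- list(rec$channel_names, rec$channel_names)
  structure(list(gamma_vals = g, P = pmat, band = ph$band),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  b <- x$band
  cat(sprintf("<connectivity_matrix> %d channels, band %s (%g-%g Hz)\n",
              nrow(x$gamma_vals),
              if (!is.null(b$name)) b$name else "?", b$lo, b$hi))
  off <- x$gamma_vals[upper.tri(x$gamma_vals)]
  cat(sprintf("  off-diagonal Gamma: min %.3f, median %.3f, max %.3f\n",
              min(off), stats::median(off), max(off)))
  invisible(x)
}

gamma_of <- function(mat) {
  if (inherits(mat, "connectivity_matrix")) mat$gamma_vals else mat
}

#' Within-system strength
#'
#' Mean Gamma over the distinct unordered channel pairs inside one
#' cognitive system. Self-pairs are excluded: including the unit diagonal
#' would floor two-channel systems (PF, O) at 0.5 and mask real coupling
#' differences.
#'
#' @param mat a [connectivity_matrix()] (or plain labeled matrix).
#' @param k system code.
#' @param parcellation a [system_parcellation()] list.
#' @return mean within-system Gamma.
#' @export
system_strength <- function(mat, k, parcellation = system_parcellation()) {
  g <- gamma_of(mat)
  chans <- intersect(parcellation[[k]], rownames(g))
  if (length(chans) < 2) abort(paste0("system ", k, " has fewer than 2 channels"))
  block <- g[chans, chans]
  mean(block[upper.tri(block)])
}

#' Between-system communication
#'
#' Mean Gamma over all channel pairs spanning two distinct cognitive
#' systems: sum of the cross-block divided by |S_k1| * |S_k2|.
#'
#' @inheritParams system_strength
#' @param k1,k2 distinct system codes.
#' @return mean cross-system Gamma.
#' @export
system_communication <- function(mat, k1, k2,
                                 parcellation = system_parcellation()) {
  if (identical(k1, k2)) abort("k1 and k2 must differ (use system_strength)")
  g <- gamma_of(mat)
  c1 <- parcellation[[k1]]; c2 <- parcellation[[k2]]
  if (is.null(c1) || is.null(c2)) abort("unknown system code")
  c1 <- intersect(c1, rownames(g)); c2 <- intersect(c2, rownames(g))
  if (length(c1) == 0 || length(c2) == 0) abort("system has no channels present")
  sum(g[c1, c2]) / (length(c1) * length(c2))
}

#' The 84-dimensional functional feature vector
#'
#' For each of the four bands: six within-system strengths plus fifteen
#' between-system communications, 21 features per band, named
#' `"<band>:<system>"` and `"<band>:<sys1>-<sys2>"`.
#'
#' @param rec a preprocessed [eeg_recording()] with the canonical montage.
#' @param bands character vector of band names (default all four).
#' @param parcellation a [system_parcellation()] list.
#' @return one-row tibble with the 84 canonical functional columns (or a
#'   subset when fewer bands are requested), all values in \[0, 1\].
#' @export
functional_features <- function(rec, bands = eeg_bands()$band,
                                parcellation = system_parcellation()) {
  sys <- names(parcellation)
  prs <- utils::combn(sys, 2)
  out <- list()
  for (b in bands) {
    cm <- connectivity_matrix(rec, b)
    for (k in sys) {
      out[[paste0(b, ":", k)]] <- system_strength(cm, k, parcellation)
    }
    for (q in seq_len(ncol(prs))) {
      k1 <- prs[1, q]; k2 <- prs[2, q]
      out[[paste0(b, ":", k1, "-", k2)]] <-
        system_communication(cm, k1, k2, parcellation)
    }
  }
  as_tibble(out)
}

#' Full 96-dimensional feature vector of one recording
#'
#' Cognitive features followed by the 84 functional features, in canonical
#' order.
#'
#' @inheritParams cognitive_features
#' @return one-row tibble with the 96 canonical feature columns.
#' @export
extract_features <- function(rec, psd = NULL, MW = NA_real_, E = NA_real_) {
  dplyr::bind_cols(cognitive_features(rec, psd = psd, MW = MW, E = E),
                   functional_features(rec))
}
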