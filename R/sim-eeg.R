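ou_phase_wander <- function(n, fs, sd, tau = 1, update_hz = 8) {
  # stationary phase deviation: an Ornstein-Uhlenbeck process with
  # stationary SD `sd` (radians) and relaxation time `tau` (s), generated
  # at a coarse rate and linearly interpolated to the sampling rate so
  # the instantaneous-frequency perturbation stays band-compatible
  nk <- max(2L, ceiling(n / fs * update_hz) + 1L)
  a <- exp(-1 / (update_hz * tau))
  innov_sd <- sd * sqrt(1 - a^2)
  knots <- numeric(nk)
  knots[1] <- rnorm(1, 0, sd)
  for (k in 2:nk) knots[k] <- a * knots[k - 1] + rnorm(1, 0, innov_sd)
  stats::approx(seq(0, n - 1, length.out = nk), knots, xout = 0:(n - 1))$y
}

#' Simulate multichannel EEG with ground-truth phase coupling
#'
#' Each channel is a sum over the four analysis bands of unit-amplitude
#' oscillators plus white noise. Within a band, a channel's phase deviates
#' from the band-centre carrier by a convex mixture with weight `g` toward
#' a shared stationary phase wander and weight `1 - g` toward its own
#' independent wander. The wander is an Ornstein-Uhlenbeck process with
#' stationary SD `wander_sd` radians and ~1 s relaxation time, so a pair
#' coupled at weight `g` has a phase-difference SD of
#' `(1 - g) * sqrt(2) * wander_sd` and its expected phase-locking value
#' follows roughly `exp(-(1 - g)^2 * wander_sd^2)`: 1 at `g = 1`, near
#' the small-sample noise floor at `g = 0`, and strictly increasing in
#' between — the generator's recovery contract.
#'
#' @param coupling tibble with columns `band` (name), `channels` (list
#'   column of channel-label vectors sharing one oscillator) and `g`
#'   (coupling weight in \[0, 1\]). Channels not mentioned for a band are
#'   fully independent in that band.
#' @param duration_s recording length in seconds (>= 2).
#' @param fs sampling rate in Hz (default 256).
#' @param channels channel labels (default the canonical 20).
#' @param noise_sd white-noise SD added per channel (default 0.1).
#' @param wander_sd stationary SD (radians) of the slow phase wander
#'   (default 2.2, placing the uncoupled-pair locking estimate near
#'   0.06 at 60 s).
#' @param seed integer seed; output is fully determined by the arguments.
#' @return list with `recording` (an [eeg_recording()]) and `truth`
#'   (the coupling tibble as given, the generator's ground-truth
#'   contract).
#' @examples
#' cp <- tibble::tibble(band = "gamma",
#'                      channels = list(c("F3", "F4")), g = 1)
#' sim <- sim_coupled_eeg(cp, duration_s = 4, channels = c("F3", "F4", "Cz"),
#'                        noise_sd = 0, seed = 1)
#' sim$recording
#' @export
sim_coupled_eeg <- function(coupling = NULL, duration_s = 60, fs = 256,
                            channels = eeg_channels(), noise_sd = 0.1,
                            wander_sd = 2.2, seed = 1) {
  n <- round(duration_s * fs)
  if (n < 2 * fs) abort("need at least 2 seconds of samples")
  set.seed(seed)
  bands <- eeg_bands()
  tt <- (0:(n - 1)) / fs
  nch <- length(channels)
  x <- matrix(0, nch, n)
  for (bi in seq_len(nrow(bands))) {
    b <- bands[bi, ]
    fc <- (b$lo + b$hi) / 2
    if (fc >= fs / 2) abort("band centre beyond Nyquist")
    carrier <- 2 * pi * fc * tt
    shared <- list()
    gvec <- rep(0, nch)
    grp <- rep(NA_integer_, nch)
    if (!is.null(coupling)) {
      rows <- which(coupling$band == b$band)
      for (ri in seq_along(rows)) {
        mem <- coupling$channels[[rows[ri]]]
        bad <- setdiff(mem, channels)
        if (length(bad)) abort(paste0("unknown channel(s): ",
                                      paste(bad, collapse = ", ")))
        gi <- coupling$g[rows[ri]]
        if (gi < 0 || gi > 1) abort("coupling g must be in [0, 1]")
        shared[[ri]] <- ou_phase_wander(n, fs, wander_sd)
        gvec[match(mem, channels)] <- gi
        grp[match(mem, channels)] <- ri
      }
    }
    for (ch in seq_len(nch)) {
      own <- ou_phase_wander(n, fs, wander_sd)
      dev <- if (!is.na(grp[ch])) {
        (1 - gvec[ch]) * own + gvec[ch] * shared[[grp[ch]]]
      } else own
      x[ch, ] <- x[ch, ] + cos(carrier + dev)
    }
  }
  if (noise_sd > 0) x <- x + matrix(rnorm(nch * n, 0, noise_sd), nch, n)
  list(
    recording = eeg_recording(x, fs = fs, channel_names = channels),
    truth = coupling
  )
}

raised_cosine <- function(len) 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))

#' Inject blink and spike artifacts with known ground truth
#'
#' Adds stereotyped frontal blink transients (raised-cosine bumps of
#' 0.5--4 Hz content) and short supra-threshold spike runs at
#' non-overlapping random positions, returning the ground-truth intervals
#' so detector recall can be measured against construction. The blink
#' count is chosen so the ground-truth blink-rate (blinked samples / N)
#' matches `blink_rate_target`.
#'
#' @param rec an [eeg_recording()].
#' @param blink_rate_target target fraction of blink-contaminated samples
#'   (default 0).
#' @param spike_count number of spike runs to inject (default 0).
#' @param blink_amp,spike_amp injection amplitudes in native units.
#' @param blink_sec blink template duration in seconds (default 0.3).
#' @param spike_lengths candidate spike run lengths (default 3, 5, 7).
#' @param frontal_channels channels receiving blink templates.
#' @param seed integer seed.
#' @return list with `recording` (artifacts added), `blink_intervals`
#'   (tibble `start`, `end`, sample indices), `spike_runs` (tibble
#'   `channel`, `start`, `length`) and `blink_mask` (ground-truth logical
#'   time vector).
#' @export
inject_artifacts <- function(rec, blink_rate_target = 0, spike_count = 0,
                             blink_amp = 30, spike_amp = 60,
                             blink_sec = 0.3, spike_lengths = c(3, 5, 7),
                             frontal_channels = c("Fp1", "Fp2", "F3", "F4"),
                             seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  set.seed(seed)
  n <- ncol(rec$samples)
  blink_len <- max(2L, round(blink_sec * rec$fs))
  n_blinks <- round(blink_rate_target * n / blink_len)
  if ((n_blinks * blink_len + spike_count * max(spike_lengths)) > n / 2) {
    abort("artifact targets infeasible for this duration")
  }
  occupied <- rep(FALSE, n)
  place <- function(len, margin = len) {
    for (try in 1:1000) {
      s <- sample.int(n - len + 1, 1)
      win <- max(1, s - margin):min(n, s + len - 1 + margin)
      if (!any(occupied[win])) {
        occupied[s:(s + len - 1)] <<- TRUE
        return(s)
      }
    }
    message("rejection sampling exhausted; overlapping injection skipped")
    NA_integer_
  }
  blink_mask <- rep(FALSE, n)
  blinks <- list()
  fidx <- channel_index(rec, intersect(frontal_channels, rec$channel_names))
  if (n_blinks > 0 && length(fidx) == 0) abort("no frontal channels to blink")
  tmpl <- blink_amp * raised_cosine(blink_len)
  for (b in seq_len(n_blinks)) {
    s <- place(blink_len)
    if (is.na(s)) next
    sel <- s:(s + blink_len - 1)
    for (ch in fidx) rec$samples[ch, sel] <- rec$samples[ch, sel] + tmpl
    blink_mask[sel] <- TRUE
    blinks[[b]] <- tibble(start = s, end = s + blink_len - 1L)
  }
  spikes <- list()
  for (k in seq_len(spike_count)) {
    len <- sample(spike_lengths, 1)
    s <- place(len, margin = max(spike_lengths))
    if (is.na(s)) next
    ch <- sample.int(nrow(rec$samples), 1)
    rec$samples[ch, s:(s + len - 1)] <-
      rec$samples[ch, s:(s + len - 1)] + spike_amp * sample(c(-1, 1), 1)
    spikes[[k]] <- tibble(channel = rec$channel_names[ch], start = s,
                          length = len)
  }
  list(recording = rec,
       blink_intervals = bind_rows(blinks),
       spike_runs = bind_rows(spikes),
       blink_mask = blink_mask)
}
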