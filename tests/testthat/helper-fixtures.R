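# small programmatic fixtures shared across test files

sine_recording <- function(freq, fs = 256, dur = 10, channels = "Cz",
                           amp = 1, phase = 0) {
  tt <- (0:(round(dur * fs) - 1)) / fs
  x <- matrix(rep(amp * sin(2 * pi * freq * tt + phase),
                  length(channels)),
              nrow = length(channels), byrow = TRUE)
  eeg_recording(x, fs = fs, channel_names = channels)
}

# two-class Gaussian feature table: `informative` columns shifted by
# `delta` between classes, the rest pure noise
blob_table <- function(n_per_class = 30, n_features = 10, informative = 1,
                       delta = 4, seed = 1, sd = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * n_features, sd = sd),
              2 * n_per_class, n_features)
  lab <- rep(c("concerning", "trustworthy"), each = n_per_class)
  x[lab == "trustworthy", seq_len(informative)] <-
    x[lab == "trustworthy", seq_len(informative)] + delta
  colnames(x) <- paste0("f", seq_len(n_features))
  d <- tibble::as_tibble(x)
  d$label <- factor(lab, levels = c("concerning", "trustworthy"))
  d
}

# direct two-line summation oracle for the synchronization index
psi_oracle <- function(dphi) {
  sqrt(sum(cos(dphi))^2 + sum(sin(dphi))^2) / length(dphi)
}
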