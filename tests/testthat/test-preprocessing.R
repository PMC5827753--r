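test_that("spike detection marks exactly the supra-threshold runs", {
  rec <- eeg_recording(matrix(0, 1, 200), channel_names = "Cz")
  expect_false(any(detect_spike_artifacts(rec)))

  rec$samples[1, 51:55] <- 50                  # 5-sample excursion
  m <- detect_spike_artifacts(rec)
  expect_identical(which(m[1, ]), 51:55)

  # excursion length not in {3,5,7}: untouched when long-run masking off
  rec2 <- eeg_recording(matrix(0, 1, 200), channel_names = "Cz")
  rec2$samples[1, 21:24] <- 50                 # 4 samples
  expect_false(any(detect_spike_artifacts(rec2, mask_long_runs = FALSE)))

  # 10-sample excursion: masked under the superset (long-run) policy
  rec3 <- eeg_recording(matrix(0, 1, 200), channel_names = "Cz")
  rec3$samples[1, 31:40] <- -50
  expect_identical(which(detect_spike_artifacts(rec3)[1, ]), 31:40)
  expect_false(any(detect_spike_artifacts(rec3, mask_long_runs = FALSE)))

  # masks never alter samples
  expect_equal(rec3$samples[1, 31], -50)
})

test_that("notch filter removes the target line and spares the passband", {
  rms <- function(r) sd(as.numeric(r$samples))
  r60 <- sine_recording(60)
  expect_lt(rms(apply_notch(r60, 60)) / rms(r60), 0.1)   # >= 20 dB
  r30 <- sine_recording(30)
  expect_gt(rms(apply_notch(r30, 60)) / rms(r30), 10^(-1 / 20))  # < 1 dB
  r10 <- sine_recording(10)
  expect_gt(rms(apply_notch(r10, 60)) / rms(r10), 0.99)
  # mixture: output approximately equals the 10 Hz component alone
  tt <- (0:2559) / 256
  mix <- eeg_recording(matrix(sin(2 * pi * 10 * tt) + sin(2 * pi * 60 * tt),
                              1), channel_names = "Cz")
  out <- apply_notch(mix, 60)
  err <- out$samples[1, ] - sin(2 * pi * 10 * tt)
  expect_lt(sqrt(mean(err^2)) / sqrt(mean(sin(2 * pi * 10 * tt)^2)), 0.05)
  expect_error(apply_notch(r10, 200), "fs/2")
})

test_that("band-pass keeps in-band and rejects out-of-band energy", {
  rms <- function(r) sd(as.numeric(r$samples))
  r6 <- sine_recording(6)
  expect_gt(rms(apply_bandpass(r6, 4, 8)) / rms(r6), 0.95)
  r20 <- sine_recording(20)
  expect_lt(rms(apply_bandpass(r20, 4, 8)) / rms(r20), 0.1)
  expect_error(apply_bandpass(r6, 4, 200), "Nyquist")
  # chirp: surviving energy concentrated in the passband
  tt <- (0:(256 * 20 - 1)) / 256
  f0 <- 1; f1 <- 100
  chirp <- sin(2 * pi * (f0 * tt + (f1 - f0) / (2 * max(tt)) * tt^2))
  rec <- eeg_recording(matrix(chirp, 1), channel_names = "Cz")
  out <- apply_bandpass(rec, 4, 8)
  psd <- compute_psd(out)
  inband <- mean(band_power(psd, 3, 9), na.rm = TRUE)
  total <- mean(band_power(psd), na.rm = TRUE)
  expect_gt(inband / total, 0.9)
})

test_that("filtering is linear in the input amplitude", {
  set.seed(42)
  rec <- eeg_recording(matrix(rnorm(1024), 1), channel_names = "Cz")
  rec3 <- rec; rec3$samples <- 3 * rec$samples
  expect_equal(apply_notch(rec3, 60)$samples,
               3 * apply_notch(rec, 60)$samples, tolerance = 1e-10)
  expect_equal(apply_bandpass(rec3, 4, 8)$samples,
               3 * apply_bandpass(rec, 4, 8)$samples, tolerance = 1e-10)
})

test_that("blink detector recovers injected blinks and stays quiet otherwise", {
  sim <- sim_coupled_eeg(NULL, duration_s = 30, seed = 11)
  clean_mask <- detect_blinks(sim$recording)
  expect_lt(mean(clean_mask[1, ]), 0.01)

  inj <- inject_artifacts(sim$recording, blink_rate_target = 0.08, seed = 3)
  m <- detect_blinks(inj$recording)
  hits <- sum(apply(inj$blink_intervals, 1, function(iv) {
    any(m[1, iv[["start"]]:iv[["end"]]])
  }))
  expect_gte(hits, ceiling(0.8 * nrow(inj$blink_intervals)))

  zero <- eeg_recording(matrix(0, 20, 512))
  expect_false(any(detect_blinks(zero)))
  one_ch <- eeg_recording(matrix(0, 1, 512), channel_names = "O1")
  expect_error(detect_blinks(one_ch), "frontal")
})

test_that("Kaiser spectrogram localizes tones and conserves power", {
  r10 <- sine_recording(10)
  psd <- compute_psd(r10)
  expect_true(all(psd$values >= 0, na.rm = TRUE))
  peaks <- apply(psd$values[1, , ], 1, function(v) psd$freq[which.max(v)])
  expect_true(all(peaks == 10))
  # window count from N, window and overlap
  nw <- 256; step <- 128
  expect_equal(dim(psd$values)[2], (2560 - nw) %/% step + 1)

  set.seed(7)
  rn <- eeg_recording(matrix(rnorm(2560, sd = 2), 1), channel_names = "Cz")
  tot <- mean(band_power(compute_psd(rn)), na.rm = TRUE)
  expect_lt(abs(tot - 4) / 4, 0.2)            # Parseval within 20%

  rz <- eeg_recording(matrix(0, 1, 512), channel_names = "Cz")
  expect_true(all(compute_psd(rz)$values == 0, na.rm = TRUE))
  short <- eeg_recording(matrix(0, 1, 100), channel_names = "Cz")
  expect_error(compute_psd(short), "shorter than one")
})

test_that("masked windows are rejected and heavy masking drops them", {
  rec <- sine_recording(10, dur = 4)
  rec$artifact_mask[1, 1:200] <- TRUE          # first window 78% masked
  psd <- compute_psd(rec)
  expect_false(psd$retained[1, 1])
  expect_true(all(is.na(psd$values[1, 1, ])))
  # light masking: window kept, interpolated
  rec2 <- sine_recording(10, dur = 4)
  rec2$artifact_mask[1, 10:20] <- TRUE
  expect_true(compute_psd(rec2)$retained[1, 1])
})

test_that("outlier removal is single-pass with the 3-SD rule", {
  expect_equal(remove_outliers(c(1, 1, 1, 1)),
               list(values = c(1, 1, 1, 1), removed = integer(0)))
  set.seed(5)
  x <- c(rnorm(100), 50)
  out <- remove_outliers(x)
  expect_identical(out$removed, 101L)
  # the classic masking example: 100 is only ~1.5 SD from this series' mean
  expect_identical(remove_outliers(c(0, 0, 0, 100))$removed, integer(0))
  # single-pass convention: applying the rule twice can remove more; one
  # call never re-iterates
  y <- c(rep(0, 20), 5, 100)
  first <- remove_outliers(y)
  second <- remove_outliers(first$values)
  expect_gt(length(second$removed), 0)          # a second pass would bite
  expect_identical(first$removed, which(abs(y - mean(y)) > 3 * sd(y)))
})
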