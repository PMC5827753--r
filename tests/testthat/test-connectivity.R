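test_that("analytic phase advances at the oscillation frequency", {
  rec <- sine_recording(10, dur = 10, channels = c("a", "b"))
  ph <- instantaneous_phase(rec, "alpha")
  expect_true(all(abs(ph$phi) <= pi + 1e-12))
  core <- 200:2300                           # avoid filter edge transients
  d <- diff(ph$phi[1, core])
  d[d < -pi] <- d[d < -pi] + 2 * pi
  slope_hz <- mean(d) * rec$fs / (2 * pi)
  expect_lt(abs(slope_hz - 10) / 10, 0.01)
  expect_equal(ph$phi[1, ], ph$phi[2, ])      # identical channels
  expect_error(instantaneous_phase(rec, list(lo = 35, hi = 200)), "Nyquist")
})

test_that("a quarter-period delay shows up as a pi/2 phase offset", {
  fs <- 256; f <- 8
  tt <- (0:(fs * 10 - 1)) / fs
  x <- sin(2 * pi * f * tt)
  y <- sin(2 * pi * f * (tt - 1 / (4 * f)))
  rec <- eeg_recording(rbind(x, y), fs = fs, channel_names = c("x", "y"))
  ph <- instantaneous_phase(rec, list(lo = 6, hi = 10))
  d <- phase_difference(ph$phi[1, 300:2200], ph$phi[2, 300:2200])
  expect_equal(mean(d), pi / 2, tolerance = 0.01)
})

test_that("phase differences are absolute and wrapped to [0, pi]", {
  expect_equal(phase_difference(c(0, 1, 2), c(0, 1, 2)), c(0, 0, 0))
  expect_equal(phase_difference(c(0, pi / 2), c(0, 0)), c(0, pi / 2))
  expect_equal(phase_difference(rep(0.7, 5), rep(0, 5)), rep(0.7, 5))
  # wrapping: a 3pi/2 raw gap is really pi/2 around the circle
  expect_equal(phase_difference(3 * pi / 2, 0), pi / 2)
  expect_error(phase_difference(1:3, 1:2), "mismatch")
})

test_that("synchronization index matches its closed forms and the oracle", {
  expect_equal(phase_sync_index(rep(0.7, 100)), 1)
  expect_equal(phase_sync_index(c(0, pi)), 0, tolerance = 1e-12)
  expect_equal(phase_sync_index(c(0, pi / 2, pi / 4)),
               sqrt((1 + 0 + cos(pi / 4))^2 + (0 + 1 + sin(pi / 4))^2) / 3)
  expect_error(phase_sync_index(numeric(0)), "no usable")
  set.seed(99)
  for (i in 1:1000) {
    d <- runif(sample(2:30, 1), -pi, pi)
    expect_equal(phase_sync_index(d), psi_oracle(d), tolerance = 1e-12)
  }
})

test_that("Gamma ignores a common phase offset", {
  set.seed(3)
  phix <- runif(500, -pi, pi)
  phiy <- runif(500, -pi, pi)
  g1 <- phase_sync_index(phix - phiy)
  g2 <- phase_sync_index((phix + 1.234) - (phiy + 1.234))
  expect_equal(g1, g2, tolerance = 1e-12)
})

test_that("connectivity matrices are symmetric, unit-diagonal and bounded", {
  sim <- sim_coupled_eeg(NULL, duration_s = 8, channels = eeg_channels()[1:6],
                         seed = 13)
  cm <- connectivity_matrix(sim$recording, "alpha")
  g <- cm$gamma_vals
  expect_equal(g, t(g))
  expect_equal(unname(diag(g)), rep(1, 6))
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(cm$P > 0))

  ident <- eeg_recording(matrix(rep(sin(2 * pi * 10 * (0:2047) / 256), 3),
                                3, byrow = TRUE),
                         channel_names = c("a", "b", "c"))
  gi <- connectivity_matrix(ident, "alpha")$gamma_vals
  expect_true(all(gi > 0.999))

  set.seed(8)
  noise <- eeg_recording(matrix(rnorm(2 * 10000), 2),
                         channel_names = c("a", "b"))
  # wide gamma band: filtering leaves ~2000 effectively independent
  # samples, so the null resultant sits well under 0.1
  expect_lt(connectivity_matrix(noise, "gamma")$gamma_vals[1, 2], 0.1)
})

test_that("masked samples are excluded pairwise with per-pair counts", {
  rec <- sine_recording(10, dur = 4, channels = c("a", "b"))
  rec$artifact_mask[1, 1:100] <- TRUE
  rec$artifact_mask[2, 50:150] <- TRUE
  cm <- connectivity_matrix(rec, "alpha")
  expect_equal(cm$P[1, 2], ncol(rec$samples) - 150)
  rec$artifact_mask[, ] <- TRUE
  expect_error(connectivity_matrix(rec, "alpha"), "fully masked")
})

test_that("strength and communication are block means of Gamma", {
  ch <- eeg_channels()
  n <- length(ch)
  set.seed(4)
  g <- matrix(runif(n * n, 0.2, 0.9), n, n)
  g <- (g + t(g)) / 2; diag(g) <- 1
  dimnames(g) <- list(ch, ch)
  parc <- system_parcellation()
  f <- parc$F
  block <- g[f, f]
  expect_equal(system_strength(g, "F"), mean(block[upper.tri(block)]))
  expect_equal(system_communication(g, "PF", "O"),
               sum(g[parc$PF, parc$O]) / 4)
  # block means live within the block's range
  expect_gte(system_strength(g, "F"), min(block[upper.tri(block)]))
  expect_lte(system_strength(g, "F"), max(block[upper.tri(block)]))
  # constant blocks give that constant
  g2 <- g; g2[parc$PF, parc$O] <- 0.5; g2[parc$O, parc$PF] <- 0.5
  expect_equal(system_communication(g2, "PF", "O"), 0.5)
  g3 <- g; g3[f, f][upper.tri(g3[f, f])] <- 0.5
  expect_error(system_communication(g, "F", "F"), "must differ")
  expect_error(system_strength(g, "Zz"), "fewer than 2|unknown")
})

test_that("the four-entry prefrontal-occipital mean is exact", {
  ch <- c("Fp1", "Fp2", "O1", "O2")
  g <- diag(1, 4); dimnames(g) <- list(ch, ch)
  g["Fp1", "O1"] <- g["O1", "Fp1"] <- 0.2
  g["Fp1", "O2"] <- g["O2", "Fp1"] <- 0.4
  g["Fp2", "O1"] <- g["O1", "Fp2"] <- 0.6
  g["Fp2", "O2"] <- g["O2", "Fp2"] <- 0.8
  expect_equal(system_communication(g, "PF", "O"), 0.5)
})

test_that("the functional feature vector has 84 bounded dimensions", {
  sim <- sim_coupled_eeg(NULL, duration_s = 8, seed = 17)
  fv <- functional_features(sim$recording)
  expect_identical(names(fv), functional_feature_names())
  expect_true(all(vapply(fv, is.finite, logical(1))))
  expect_true(all(fv >= 0 & fv <= 1))

  ident <- eeg_recording(matrix(rep(rowSums(sapply(c(6, 10, 20, 45),
                                                   function(f) sin(2 * pi * f * (0:4095) / 256))), 20),
                                20, byrow = TRUE))
  fvi <- functional_features(ident)
  expect_true(all(fvi > 0.999))
})

test_that("band-specific coupling elevates only that band's features", {
  parc <- system_parcellation()
  cp <- tibble::tibble(band = "gamma", channels = list(parc$F), g = 1)
  sim <- sim_coupled_eeg(cp, duration_s = 20, seed = 19)
  fv <- functional_features(sim$recording)
  expect_gt(fv[["gamma:F"]], 0.9)
  expect_lt(fv[["theta:F"]], 0.4)
  expect_lt(fv[["alpha:F"]], 0.4)
  expect_lt(fv[["beta:F"]], 0.4)
})
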