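test_that("group specs encode the printed summaries with SE-to-SD conversion", {
  uva <- uva_group_spec()
  expect_equal(uva$n_trustworthy, 63)
  expect_equal(uva$n_concerning, 24)
  row <- uva$table[uva$table$feature == "gamma:F", ]
  expect_equal(row$mean_trustworthy, 0.37)
  expect_equal(row$sd_trustworthy, 0.01 * sqrt(63))
  expect_equal(row$mean_concerning, 0.75)
  expect_equal(row$sd_concerning, 0.03 * sqrt(24))

  lnd <- lnd_group_spec()
  expect_equal(c(lnd$n_trustworthy, lnd$n_concerning), c(43, 40))
  br <- lnd$table[lnd$table$feature == "BR", ]
  expect_equal(br$mean_concerning, 0.71)
  expect_equal(br$sd_concerning, 0.02 * sqrt(40))
  expect_length(lnd$key_features, 9)
  # printed SE of 0.00 is floored, keeping every SD positive
  fo <- lnd$table[lnd$table$feature == "gamma:F-O", ]
  expect_equal(fo$sd_trustworthy, 0.005 * sqrt(43))
  expect_true(all(lnd$table$sd_trustworthy > 0))

  # non-key features carry no group difference
  nk <- uva$table[!uva$table$key, ]
  expect_equal(nk$mean_trustworthy, nk$mean_concerning)
})

test_that("feature datasets are seed-deterministic with legal ranges", {
  d1 <- sim_feature_dataset(lnd_group_spec(), seed = 7)
  d2 <- sim_feature_dataset(lnd_group_spec(), seed = 7)
  expect_identical(d1, d2)
  expect_equal(nrow(d1), 83)
  expect_equal(sum(d1$label == "trustworthy"), 43)
  expect_identical(setdiff(names(d1), c("recording_id", "task", "label")),
                   feature_names())
  rng <- feature_ranges()
  for (i in seq_len(nrow(rng))) {
    v <- d1[[rng$feature[i]]]
    expect_true(all(v >= rng$lo[i] & v <= rng$hi[i]))
  }
  d3 <- sim_feature_dataset(lnd_group_spec(), seed = 8)
  expect_false(identical(d1[["gamma:F"]], d3[["gamma:F"]]))
})

test_that("sample means converge to spec means at large n", {
  spec <- uva_group_spec()
  d <- sim_feature_dataset(spec, seed = 9, n_trustworthy = 4000,
                           n_concerning = 4000)
  tr <- d[d$label == "trustworthy", ]
  # unclipped, well-interior features converge at the 3 SD / sqrt(n) scale
  for (f in c("gamma:F", "gamma:F-Pa", "ML_F", "SA")) {
    row <- spec$table[spec$table$feature == f, ]
    expect_lt(abs(mean(tr[[f]]) - row$mean_trustworthy),
              3 * row$sd_trustworthy / sqrt(4000) + 1e-3)
  }
})

test_that("zero-SD specs give separable point clouds", {
  spec <- uva_group_spec()
  spec$table$sd_trustworthy[] <- 1e-12
  spec$table$sd_concerning[] <- 1e-12
  d <- sim_feature_dataset(spec, seed = 10)
  expect_equal(sd(d[["gamma:F"]][d$label == "trustworthy"]), 0,
               tolerance = 1e-9)
  ev <- evaluate_svm(d, spec$key_features, cv = "loocv")
  expect_equal(ev$accuracy, 100)
})

test_that("key features separate significantly across repeated seeds", {
  spec <- lnd_group_spec()
  fun_keys <- grep("^gamma", spec$key_features, value = TRUE)
  hits <- sapply(1:20, function(s) {
    d <- sim_feature_dataset(spec, seed = 200 + s)
    res <- group_ttest(d, spec$key_features)
    c(fun_br = all(res$p_adj[res$feature %in% c(fun_keys, "BR")] < 0.05),
      ai_raw = res$p[res$feature == "AI"] < 0.05,
      ai_adj = res$p_adj[res$feature == "AI"] < 0.05)
  })
  # strong printed effects (d ~ 3-4 functional, ~1 BR) survive Bonferroni
  expect_gte(mean(hits["fun_br", ]), 0.95)
  # AI's printed group gap is ~3.6 SE: reliably significant uncorrected,
  # and clears the corrected threshold at the power that gap affords
  expect_gte(mean(hits["ai_raw", ]), 0.9)
  expect_gte(mean(hits["ai_adj", ]), 0.5)
})

test_that("an optional correlation matrix induces the requested dependence", {
  cm <- matrix(c(1, -0.56, -0.56, 1), 2,
               dimnames = list(c("gamma:F", "E"), c("gamma:F", "E")))
  d <- sim_feature_dataset(uva_group_spec(), seed = 11,
                           n_trustworthy = 2000, n_concerning = 2,
                           cor_matrix = cm)
  tr <- d[d$label == "trustworthy", ]
  expect_lt(abs(cor(tr[["gamma:F"]], tr[["E"]]) + 0.56), 0.08)
})

test_that("coupled-oscillator recordings honour their locking contract", {
  cp <- tibble::tibble(band = "gamma", channels = list(c("F3", "F4")), g = 1)
  sim <- sim_coupled_eeg(cp, duration_s = 10, channels = c("F3", "F4"),
                         noise_sd = 0, seed = 12)
  expect_gt(connectivity_matrix(sim$recording, "gamma")$gamma_vals[1, 2],
            0.99)
  # determinism
  sim2 <- sim_coupled_eeg(cp, duration_s = 10, channels = c("F3", "F4"),
                          noise_sd = 0, seed = 12)
  expect_identical(sim$recording$samples, sim2$recording$samples)
  # uncoupled pairs sit at the noise floor on average
  g0 <- vapply(1:5, function(s) {
    s0 <- sim_coupled_eeg(NULL, duration_s = 30, channels = c("F3", "F4"),
                          seed = s)
    connectivity_matrix(s0$recording, "gamma")$gamma_vals[1, 2]
  }, numeric(1))
  expect_lt(mean(g0), 0.15)
  expect_error(sim_coupled_eeg(cp, duration_s = 1), "2 seconds")
  bad <- tibble::tibble(band = "gamma", channels = list("Qq"), g = 0.5)
  expect_error(sim_coupled_eeg(bad, duration_s = 4,
                               channels = c("F3", "F4")), "unknown channel")
})

test_that("artifact injection meets its blink-rate and spike contracts", {
  sim <- sim_coupled_eeg(NULL, duration_s = 30, seed = 14)
  inj <- inject_artifacts(sim$recording, blink_rate_target = 0.1,
                          spike_count = 5, seed = 15)
  expect_lt(abs(mean(inj$blink_mask) - 0.1), 0.01)
  expect_equal(nrow(inj$spike_runs), 5)
  expect_true(all(inj$spike_runs$length %in% c(3, 5, 7)))
  # detector recovers at least 4 of the 5 runs
  m <- detect_spike_artifacts(inj$recording, amp_threshold = 40)
  hits <- sum(apply(inj$spike_runs, 1, function(r) {
    ch <- match(r[["channel"]], inj$recording$channel_names)
    s <- as.integer(r[["start"]])
    any(m[ch, s:(s + as.integer(r[["length"]]) - 1)])
  }))
  expect_gte(hits, 4)
  # zero targets leave the recording untouched
  same <- inject_artifacts(sim$recording, 0, 0, seed = 16)
  expect_identical(same$recording$samples, sim$recording$samples)
  expect_equal(nrow(same$blink_intervals), 0)
})
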