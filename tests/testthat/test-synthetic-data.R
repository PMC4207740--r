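test_that("an absorbing WAKE row yields an all-WAKE hypnogram", {
  P <- matrix(
    c(
      1, 0, 0,
      0.025, 0.95, 0.025,
      0.08, 0.02, 0.90
    ),
    3, 3,
    byrow = TRUE,
    dimnames = list(c("WAKE", "NREM", "REM"), c("WAKE", "NREM", "REM"))
  )
  cfg <- sim_config(recording_days = 1, base_transition_matrix = P)
  hyp <- simulate_hypnogram(cfg, "WT", seed = 4, n_epochs = 2000)
  expect_true(all(hyp$state == "WAKE"))
})

test_that("hypnogram simulation is deterministic given (config, group, seed)", {
  cfg <- sim_config(recording_days = 1)
  h1 <- simulate_hypnogram(cfg, "MUT", seed = 11)
  h2 <- simulate_hypnogram(cfg, "MUT", seed = 11)
  expect_identical(h1$state, h2$state)
  expect_identical(h1$artifact, h2$artifact)
  h3 <- simulate_hypnogram(cfg, "MUT", seed = 12)
  expect_false(identical(h1$state, h3$state))
})

test_that("without modulation, empirical transition frequencies match the base matrix", {
  cfg <- sim_config(
    recording_days = 1,
    diurnal_modulation_depth = c(WT = 0, MUT = 0)
  )
  hyp <- simulate_hypnogram(cfg, "WT", seed = 3, n_epochs = 21600)
  counts <- oracle_transition_freqs(hyp$state)
  P <- cfg$base_transition_matrix
  for (i in 1:3) {
    n_i <- sum(counts[i, ])
    for (j in 1:3) {
      se <- sqrt(P[i, j] * (1 - P[i, j]) / n_i)
      expect_lt(abs(counts[i, j] / n_i - P[i, j]), 3 * se + 1e-12)
    }
  }
  # chi-square goodness of fit per row, not rejected at alpha = 0.01
  for (i in 1:3) {
    keep <- P[i, ] > 0
    stat <- sum((counts[i, keep] - sum(counts[i, ]) * P[i, keep])^2 /
      (sum(counts[i, ]) * P[i, keep]))
    expect_lt(stat, qchisq(0.99, df = sum(keep) - 1))
  }
})

test_that("modulated transition probabilities exceeding 1 raise a config error", {
  P <- matrix(
    c(
      0.2, 0.8, 0,
      0.025, 0.95, 0.025,
      0.08, 0.02, 0.90
    ),
    3, 3,
    byrow = TRUE,
    dimnames = list(c("WAKE", "NREM", "REM"), c("WAKE", "NREM", "REM"))
  )
  expect_error(
    sim_config(base_transition_matrix = P, diurnal_modulation_depth = c(WT = 0.4)),
    "Modulated"
  )
})

test_that("sleep deprivation enforces wakefulness at the requested efficiency", {
  hyp <- uniform_hypnogram("NREM", 5400)
  all_wake <- apply_sleep_deprivation(hyp, c(0, 6), 1.0, seed = 1)
  expect_true(all(all_wake$state == "WAKE"))

  untouched <- apply_sleep_deprivation(hyp, c(0, 6), 0.0, seed = 1)
  expect_identical(untouched$state, hyp$state)

  sd97 <- apply_sleep_deprivation(hyp, c(0, 6), 0.97, seed = 2)
  frac <- mean(sd97$state == "WAKE")
  se <- sqrt(0.97 * 0.03 / 5400)
  expect_lt(abs(frac - 0.97), 3 * se)

  expect_error(apply_sleep_deprivation(hyp, c(0, 6), 1.2, seed = 1), "efficiency")
  expect_error(apply_sleep_deprivation(hyp, c(5, 9), 0.9, seed = 1), "span")
})

test_that("NREM signal epochs are delta-dominated (independent periodogram)", {
  cfg <- sim_config(homeostat_enabled = FALSE)
  hyp <- uniform_hypnogram("NREM", 200)
  rec <- synthesize_signals(hyp, cfg, "WT", seed = 5, channels = "EEG")
  spe <- 1024
  wins <- vapply(seq_len(200), function(e) {
    x <- rec$channels$EEG[((e - 1) * spe + 1):(e * spe)]
    oracle_band_power(x, 0.5, 4) > oracle_band_power(x, 5, 10)
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("REM theta at 7.5 Hz lands in the right spectral bin", {
  cfg <- sim_config(theta_center_frequency = c(WT = 7.5, MUT = 7.5))
  hyp <- uniform_hypnogram("REM", 300)
  rec <- synthesize_signals(hyp, cfg, "WT", seed = 6, channels = "EEG")
  spe <- 1024
  acc <- 0
  for (e in seq_len(300)) {
    sp <- oracle_epoch_spectrum(rec$channels$EEG[((e - 1) * spe + 1):(e * spe)])
    acc <- acc + sp$power
  }
  freq <- sp$frequency
  sel <- freq >= 5 & freq <= 10
  peak <- freq[sel][which.max(acc[sel])]
  expect_lte(abs(peak - 7.5), 0.5)
})

test_that("a zero-length hypnogram gives an empty recording with valid metadata", {
  cfg <- sim_config()
  hyp <- hypnogram(character(0))
  rec <- synthesize_signals(hyp, cfg, "WT", seed = 1)
  expect_equal(rec$n_epochs, 0)
  expect_equal(length(rec$channels$EEG), 0)
  expect_equal(rec$sampling_rate, cfg$sampling_rate)
})

test_that("theta centers outside the analysis band are rejected", {
  cfg <- sim_config(theta_center_frequency = c(WT = 25))
  expect_error(
    synthesize_signals(uniform_hypnogram("REM", 2), cfg, "WT", seed = 1),
    "analysis band"
  )
})

test_that("EMG amplitude follows WAKE > NREM > REM", {
  cfg <- sim_config()
  rms_of <- function(state) {
    rec <- synthesize_signals(uniform_hypnogram(state, 50), cfg, "WT", seed = 9)
    sqrt(mean(rec$channels$EMG^2))
  }
  expect_gt(rms_of("WAKE"), rms_of("NREM"))
  expect_gt(rms_of("NREM"), rms_of("REM"))
})

test_that("artifact epochs carry a high-amplitude transient but keep their label", {
  cfg <- sim_config()
  hyp <- hypnogram(rep("NREM", 20), artifact = c(rep(FALSE, 19), TRUE))
  rec <- synthesize_signals(hyp, cfg, "WT", seed = 2, channels = "EEG")
  spe <- 1024
  amp_art <- max(abs(rec$channels$EEG[(19 * spe + 1):(20 * spe)]))
  amp_clean <- max(abs(rec$channels$EEG[1:spe]))
  expect_gt(amp_art, 2 * amp_clean)
  expect_identical(hyp$state[20], "NREM")
})

test_that("wheel activity follows the configured Poisson design", {
  cfg0 <- sim_config(wheel_rate_light = 0, wheel_rate_dark = c(WT = 0))
  s0 <- simulate_wheel_activity(cfg0, "WT", seed = 1, n_days = 1)
  expect_true(all(s0$count == 0))

  cfg1 <- sim_config(wheel_rate_light = 0, wheel_rate_dark = c(WT = 10))
  s1 <- simulate_wheel_activity(cfg1, "WT", seed = 2, n_days = 5)
  light <- s1$zt %% 24 < 12
  expect_true(all(s1$count[light] == 0))
  dark_mean <- mean(s1$count[!light])
  se <- sqrt(10 / sum(!light))
  expect_lt(abs(dark_mean - 10), 3 * se)

  expect_identical(
    simulate_wheel_activity(cfg1, "WT", seed = 3, n_days = 1)$count,
    simulate_wheel_activity(cfg1, "WT", seed = 3, n_days = 1)$count
  )
})

test_that("expression simulation plants exact effects and is reproducible", {
  cfg <- sim_config(
    expression_n_genes = 40, expression_noise_sd = 0,
    expression_effect_log2fc = 1, expression_attenuation = 0.3
  )
  em <- simulate_expression(cfg, seed = 1)
  night <- em$samples$timepoint == "ZT16" & em$samples$genotype == "WT"
  day <- em$samples$timepoint == "ZT4" & em$samples$genotype == "WT"
  diffs <- rowMeans(em$values[em$planted, night]) -
    rowMeans(em$values[em$planted, day])
  expect_equal(unname(diffs), rep(1, length(em$planted)))

  em2 <- simulate_expression(cfg, seed = 1)
  expect_identical(em$values, em2$values)

  expect_error(
    simulate_expression(sim_config(expression_n_replicates = 2), seed = 1),
    NA
  )
  expect_error(sim_config(expression_n_replicates = 1), "replicates")
})

test_that("the homeostat rises through enforced wakefulness and rebounds", {
  cfg <- sim_config(recording_days = 1)
  hyp <- simulate_hypnogram(cfg, "WT", seed = 21)
  hyp_sd <- apply_sleep_deprivation(hyp, c(0, 6), 0.97, seed = 22)
  s_base <- homeostat_trajectory(hyp)
  s_sd <- homeostat_trajectory(hyp_sd)
  at_zt6 <- 6 * 900 # epoch index at ZT6 for 4-s epochs
  expect_gt(s_sd[at_zt6], s_base[at_zt6])
})

test_that("per-animal substreams are stable under cohort growth", {
  cfg_small <- sim_config(n_animals_per_group = 2, recording_days = 1)
  cfg_big <- sim_config(n_animals_per_group = 3, recording_days = 1)
  co1 <- simulate_cohort(cfg_small,
    seed = 5, sleep_deprivation = FALSE,
    wheel_days = 0, expression = FALSE
  )
  co2 <- simulate_cohort(cfg_big,
    seed = 5, sleep_deprivation = FALSE,
    wheel_days = 0, expression = FALSE
  )
  for (id in c("WT_01", "WT_02", "MUT_01", "MUT_02")) {
    expect_identical(co1$hypnograms[[id]]$state, co2$hypnograms[[id]]$state)
  }
})
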