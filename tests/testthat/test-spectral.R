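epoch_time <- function(fs = 256, secs = 4) (seq_len(fs * secs) - 1) / fs

test_that("pure tones peak in the correct spectral bin", {
  t <- epoch_time()
  sp <- epoch_spectrum(sin(2 * pi * 8 * t))
  expect_equal(sp$frequency[which.max(sp$power)], 8)

  zero <- epoch_spectrum(rep(0, 1024))
  expect_true(all(zero$power == 0))

  two <- epoch_spectrum(sin(2 * pi * 2 * t) + sin(2 * pi * 7.5 * t))
  local_max <- function(p, i) p[i] > p[i - 1] && p[i] > p[i + 1]
  i2 <- which(two$frequency == 2)
  i75 <- which(two$frequency == 7.5)
  expect_true(local_max(two$power, i2))
  expect_true(local_max(two$power, i75))
})

test_that("epoch_spectrum rejects malformed epochs", {
  expect_error(epoch_spectrum(rnorm(1000)), "1024")
  expect_error(epoch_spectrum(c(rnorm(1023), NA)), "finite")
})

test_that("epoch_spectrum agrees with the direct-DFT oracle", {
  set.seed(31)
  for (i in seq_len(50)) {
    x <- rnorm(1024)
    mine <- epoch_spectrum(x)
    orc <- oracle_epoch_spectrum(x)
    expect_equal(mine$frequency, orc$frequency)
    expect_lt(max(abs(mine$power - orc$power)) / max(orc$power), 1e-9)
  }
})

test_that("the 4-s periodogram option folds onto the same grid", {
  t <- epoch_time()
  sp <- epoch_spectrum(sin(2 * pi * 8 * t), method = "fft4s")
  expect_equal(sp$frequency, seq(0.5, 20, by = 0.5))
  expect_equal(sp$frequency[which.max(sp$power)], 8)
})

test_that("full-band spectra satisfy Parseval with the Hann power correction", {
  set.seed(7)
  x <- rnorm(1024)
  sp <- epoch_spectrum(x, full_band = TRUE)
  w <- 0.5 * (1 - cos(2 * pi * (0:511) / 512))
  ms <- mean(c(
    sum((x[1:512] * w)^2) / sum(w^2),
    sum((x[513:1024] * w)^2) / sum(w^2)
  )) * 512
  expect_lt(abs(sum(sp$power) * 0.5 - ms / 512) / (ms / 512), 1e-6)
})

test_that("band power is the inclusive-bin arithmetic mean", {
  flat <- tibble::tibble(frequency = seq(0.5, 20, 0.5), power = 3)
  expect_equal(band_power(flat, 0.5, 4), 3)
  expect_equal(band_power(flat, 5, 10), 3)

  one <- tibble::tibble(
    frequency = seq(0.5, 20, 0.5),
    power = as.numeric(seq(0.5, 20, 0.5) == 2)
  )
  expect_equal(band_power(one, 0.5, 4), 1 / 8)

  set.seed(2)
  rnd <- tibble::tibble(frequency = seq(0.5, 20, 0.5), power = runif(40))
  expect_equal(
    band_power(rnd, 4.5, 11),
    mean(rnd$power[rnd$frequency >= 4.5 & rnd$frequency <= 11])
  )
  expect_error(band_power(rnd, 0.1, 4), "outside")
  expect_error(band_power(rnd, 6, 5), "lo")
})

make_constant_recording <- function(n_epochs, states = rep("NREM", n_epochs)) {
  # identical waveform in every epoch -> constant per-epoch SWA
  t <- epoch_time()
  epoch_sig <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 9 * t)
  rec <- epoched_recording(list(EEG = rep(epoch_sig, n_epochs)))
  hyp <- hypnogram(states)
  list(rec = rec, hyp = hyp)
}

test_that("the SWA reference is the mean over the last 900 qualifying epochs", {
  cr <- make_constant_recording(950)
  ref <- swa_reference(cr$rec, cr$hyp)
  expect_equal(ref, band_power(epoch_spectrum(cr$rec$channels$EEG[1:1024]), 0.5, 4))

  cr2 <- make_constant_recording(899)
  expect_error(swa_reference(cr2$rec, cr2$hyp), "899")

  # reduced reference window is allowed but logged
  expect_message(
    ref2 <- swa_reference(cr2$rec, cr2$hyp, n_epochs = 800),
    "reduced"
  )
  expect_equal(ref2, ref)
})

test_that("the reference uses the chronologically last epochs, light phase only", {
  cfg <- sim_config(recording_days = 1, sampling_rate = 128)
  hyp <- simulate_hypnogram(cfg, "WT", seed = 17)
  rec <- synthesize_signals(hyp, cfg, "WT", seed = 18, channels = "EEG")
  ref <- swa_reference(rec, hyp)
  ok <- which(hyp$state == "NREM" & !hyp$artifact & hyp$zt < 12)
  last900 <- tail(ok, 900)
  manual <- mean(chronosleep:::swa_per_epoch(rec, last900))
  expect_equal(ref, manual)
  # normalization identity: the reference window itself averages to 100
  swa <- chronosleep:::swa_per_epoch(rec, last900)
  expect_lt(abs(mean(swa / ref * 100) - 100), 1e-9)
})

test_that("SWA time courses normalize to the reference and flag empty bins", {
  cr <- make_constant_recording(1800)
  ref <- swa_reference(cr$rec, cr$hyp, n_epochs = 900)
  tc <- swa_timecourse(cr$rec, cr$hyp, ref, bin_hours = 1)
  expect_true(all(abs(tc$swa_pct - 100) < 1e-9))

  # second hour has no NREM at all -> missing, not zero
  states <- rep(c("NREM", "WAKE"), each = 900)
  cr2 <- make_constant_recording(1800, states)
  ref2 <- swa_reference(cr2$rec, cr2$hyp, n_epochs = 900)
  tc2 <- swa_timecourse(cr2$rec, cr2$hyp, ref2, bin_hours = 1)
  expect_true(tc2$missing[2])
  expect_true(is.na(tc2$swa_pct[2]))
  expect_error(swa_timecourse(cr2$rec, cr2$hyp, reference = 0), "positive")
})

test_that("state-conditional mean spectra average bin-wise", {
  t <- epoch_time()
  e1 <- sin(2 * pi * 3 * t)
  e2 <- sin(2 * pi * 7 * t)
  rec <- epoched_recording(list(EEG = c(e1, e2, e1)))
  hyp <- hypnogram(c("REM", "REM", "WAKE"))

  single <- mean_state_spectrum(
    epoched_recording(list(EEG = e1)), hypnogram("REM"), "REM"
  )
  expect_equal(single$power, epoch_spectrum(e1)$power)

  both <- mean_state_spectrum(rec, hyp, "REM")
  expect_equal(
    both$power,
    (epoch_spectrum(e1)$power + epoch_spectrum(e2)$power) / 2
  )
  expect_equal(attr(both, "n_epochs_averaged"), 2L)
  expect_error(mean_state_spectrum(rec, hyp, "NREM"), "NREM")
})

test_that("artifact-flagged epochs are excluded from spectral averages", {
  t <- epoch_time()
  e1 <- sin(2 * pi * 3 * t)
  e2 <- 50 * sin(2 * pi * 15 * t)
  rec <- epoched_recording(list(EEG = c(e1, e2)))
  hyp <- hypnogram(c("REM", "REM"), artifact = c(FALSE, TRUE))
  sp <- mean_state_spectrum(rec, hyp, "REM")
  expect_equal(sp$power, epoch_spectrum(e1)$power)
})

test_that("theta peak frequency stays on the grid with low-frequency tie-break", {
  grid <- seq(0.5, 20, 0.5)
  p <- rep(0.1, 40)
  p[grid == 7.5] <- 1
  expect_equal(theta_peak_frequency(tibble::tibble(frequency = grid, power = p))$tpf, 7.5)

  p2 <- rep(0.1, 40)
  p2[grid == 7] <- 1
  p2[grid == 7.5] <- 1
  expect_equal(theta_peak_frequency(tibble::tibble(frequency = grid, power = p2))$tpf, 7)

  expect_error(
    theta_peak_frequency(tibble::tibble(frequency = grid, power = rep(0, 40))),
    "All-zero"
  )

  # grid closure on simulated REM spectra
  cfg <- sim_config(theta_center_frequency = c(WT = 6.8))
  hyp <- uniform_hypnogram("REM", 400)
  rec <- synthesize_signals(hyp, cfg, "WT", seed = 3, channels = "EEG")
  tpf <- theta_peak_frequency(mean_state_spectrum(rec, hyp, "REM"))$tpf
  expect_true(tpf %in% seq(5, 10, 0.5))
})

test_that("spectra scale as amplitude squared; normalized SWA and TPF are invariant", {
  cfg <- sim_config(sampling_rate = 128)
  hyp <- simulate_hypnogram(
    sim_config(recording_days = 1, sampling_rate = 128), "WT",
    seed = 23, n_epochs = 2700
  )
  rec <- synthesize_signals(hyp, cfg, "WT", seed = 24, channels = "EEG")
  k <- 3.7
  rec_k <- epoched_recording(list(EEG = k * rec$channels$EEG),
    sampling_rate = 128
  )
  e <- which(hyp$state == "NREM")[1]
  x <- rec$channels$EEG[((e - 1) * 512 + 1):(e * 512)]
  sp1 <- epoch_spectrum(x, sampling_rate = 128)
  sp2 <- epoch_spectrum(k * x, sampling_rate = 128)
  expect_equal(sp2$power, k^2 * sp1$power, tolerance = 1e-12)

  suppressMessages({
    ref1 <- swa_reference(rec, hyp, n_epochs = 500)
    ref2 <- swa_reference(rec_k, hyp, n_epochs = 500)
  })
  tc1 <- swa_timecourse(rec, hyp, ref1, bin_hours = 1)
  tc2 <- swa_timecourse(rec_k, hyp, ref2, bin_hours = 1)
  expect_equal(tc1$swa_pct, tc2$swa_pct, tolerance = 1e-9)

  tpf1 <- theta_peak_frequency(mean_state_spectrum(rec, hyp, "REM"))$tpf
  tpf2 <- theta_peak_frequency(mean_state_spectrum(rec_k, hyp, "REM"))$tpf
  expect_equal(tpf1, tpf2)
})
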