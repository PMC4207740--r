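#' Epoched multichannel recording
#'
#' Container for synthetic (or imported) EEG/EMG signals aligned to a light
#' schedule and sliced into scoring epochs. Channels are plain numeric vectors
#' in arbitrary but consistent amplitude units.
#'
#' @param channels Named list of equal-length numeric vectors (e.g. EEG, EMG).
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_seconds Scoring epoch length in seconds.
#' @param start_zt ZT hour of the first sample.
#' @param schedule A [light_schedule()].
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(channels, sampling_rate = 256, epoch_seconds = 4,
                              start_zt = 0, schedule = light_schedule()) {
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) > 1) abort("All channels must have equal length.")
  spe <- sampling_rate * epoch_seconds
  if (length(lens) > 0 && lens[1] %% spe != 0) {
    abort("Channel length must be an integer multiple of epoch_seconds * sampling_rate.")
  }
  structure(
    list(
      channels = channels,
      sampling_rate = sampling_rate,
      epoch_seconds = epoch_seconds,
      start_zt = start_zt,
      schedule = schedule,
      n_epochs = if (length(lens) > 0) unname(lens[1]) %/% spe else 0L
    ),
    class = "epoched_recording"
  )
}

#' @export
print.epoched_recording <- function(x, ...) {
  cat(sprintf(
    "<epoched_recording> %d epochs x %g s @ %g Hz; channels: %s\n",
    x$n_epochs, x$epoch_seconds, x$sampling_rate,
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

# Direct-form IIR filtering, identical to signal::filter(Arma(b, a), x);
# compiled because recordings run to tens of millions of samples.
iir_filter <- function(x, b, a) {
  iir_filter_cpp(x, b, a)
}

# Squared magnitude response of an IIR filter on a frequency grid.
iir_response2 <- function(b, a, f, fs) {
  vapply(f, function(ff) {
    z <- exp(-2i * pi * ff / fs)
    Mod(sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1)))^2
  }, numeric(1))
}

# Pink (1/f) noise floor, unit variance: white noise through the classic
# 3-pole/3-zero pinking approximation (|H|^2 * f flat to ~10% over
# 0.25-100 Hz at fs = 256), rescaled analytically to unit variance.
PINK_B <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
PINK_A <- c(1, -2.494956002, 2.017265875, -0.522189400)

pink_noise <- function(n, fs) {
  if (n == 0) {
    return(numeric(0))
  }
  grid <- seq(0, fs / 2, length.out = 2049)
  v <- mean(iir_response2(PINK_B, PINK_A, grid, fs)) # output variance, unit white in
  iir_filter(rnorm(n), PINK_B, PINK_A) / sqrt(v)
}

# 4th-order Butterworth band-pass of white noise, rescaled to approximately
# unit variance (white noise has flat PSD, so the passband retains a
# bandwidth/(fs/2) fraction of the input power).
bandlimited_noise <- function(n, lo, hi, fs) {
  if (n == 0) {
    return(numeric(0))
  }
  bf <- signal::butter(2, c(lo, hi) / (fs / 2), type = "pass")
  iir_filter(rnorm(n), bf$b, bf$a) * sqrt(fs / (2 * (hi - lo)))
}

#' Synthesize state-conditional EEG/EMG signals for a hypnogram
#'
#' Every epoch receives a pink-noise (1/f) floor. NREM epochs add 0.5-4 Hz
#' band-limited noise with amplitude `delta_gain * (0.5 + S)`, where S is the
#' homeostat state from [homeostat_trajectory()] (constant 0.5 when the
#' homeostat is disabled) — so slow-wave activity tracks sleep pressure. REM
#' epochs add a narrowband theta oscillation: white noise band-passed
#' (4th-order Butterworth) to `theta_center_frequency +/- theta_bandwidth/2`.
#' WAKE epochs add broadband noise. The EMG channel is white noise whose RMS
#' follows WAKE > NREM > REM, and artifact-flagged epochs receive a
#' high-amplitude transient on both channels.
#'
#' @param hyp A [hypnogram()].
#' @param config A [sim_config()] consistent with the hypnogram's epoching.
#' @param group Group label selecting the theta center frequency.
#' @param seed Integer seed; deterministic given (hypnogram, config, seed).
#' @param channels Channels to synthesize; dropping `"EMG"` saves time when
#'   only the EEG is analyzed (the EEG stream is unaffected).
#' @return An [epoched_recording()] with the requested channels.
#' @examples
#' cfg <- sim_config(recording_days = 1)
#' hyp <- hypnogram(rep("REM", 30))
#' rec <- synthesize_signals(hyp, cfg, "WT", seed = 1)
#' rec
#' @export
synthesize_signals <- function(hyp, config, group = "WT", seed = 1,
                               channels = c("EEG", "EMG")) {
  stopifnot(inherits(config, "sim_config"))
  hyp <- as_hypnogram(hyp)
  fs <- config$sampling_rate
  eps <- config$epoch_seconds
  if (abs(epoch_seconds(hyp) - eps) > 1e-9) {
    abort("Hypnogram epoch length disagrees with the configuration.")
  }
  f0 <- group_param(config$theta_center_frequency, group, "theta_center_frequency")
  if (f0 <= 0.5 || f0 >= 20) {
    abort("`theta_center_frequency` must lie inside the analysis band (0.5, 20) Hz.")
  }
  n <- nrow(hyp)
  spe <- as.integer(fs * eps)
  if (n == 0) {
    empty <- setNames(rep(list(numeric(0)), length(channels)), channels)
    return(epoched_recording(empty,
      sampling_rate = fs, epoch_seconds = eps,
      start_zt = hyp_start_zt(hyp), schedule = hyp_schedule(hyp)
    ))
  }

  s <- if (isTRUE(config$homeostat_enabled)) {
    homeostat_trajectory(hyp, config$homeostat_rise_tau, config$homeostat_decay_tau)
  } else {
    rep(0.5, n)
  }

  is_wake <- hyp$state == "WAKE"
  is_nrem <- hyp$state == "NREM"
  is_rem <- hyp$state == "REM"

  with_rng(seed, {
    eeg <- pink_noise(n * spe, fs)

    delta_amp <- ifelse(is_nrem, config$delta_gain * (0.5 + s), 0)
    eeg <- eeg + bandlimited_noise(n * spe, 0.5, 4, fs) * rep(delta_amp, each = spe)

    theta_amp <- ifelse(is_rem, config$theta_gain, 0)
    eeg <- eeg + bandlimited_noise(
      n * spe, f0 - config$theta_bandwidth / 2,
      f0 + config$theta_bandwidth / 2, fs
    ) * rep(theta_amp, each = spe)

    wake_amp <- ifelse(is_wake, config$wake_gain, 0)
    eeg <- eeg + rnorm(n * spe) * rep(wake_amp, each = spe)

    # artifact epochs: short high-amplitude burst in the middle of the epoch
    art_idx <- which(hyp$artifact)
    burst_pos <- integer(0)
    if (length(art_idx) > 0) {
      burst_len <- max(8L, spe %/% 16L)
      offs <- (spe - burst_len) %/% 2L
      burst_pos <- as.vector(
        outer(seq_len(burst_len), (art_idx - 1L) * spe + offs, `+`)
      )
      eeg[burst_pos] <- eeg[burst_pos] + rnorm(length(burst_pos), sd = 15)
    }

    out_channels <- list(EEG = eeg)
    if ("EMG" %in% channels) { # drawn last so the EEG stream is unaffected
      emg_amp <- c(WAKE = 1, NREM = 0.4, REM = 0.15)[hyp$state]
      emg <- rnorm(n * spe) * rep(unname(emg_amp), each = spe)
      if (length(burst_pos) > 0) {
        emg[burst_pos] <- emg[burst_pos] + rnorm(length(burst_pos), sd = 15)
      }
      out_channels$EMG <- emg
    }
    epoched_recording(out_channels[channels[channels %in% names(out_channels)]],
      sampling_rate = fs, epoch_seconds = eps,
      start_zt = hyp_start_zt(hyp), schedule = hyp_schedule(hyp)
    )
  })
}
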