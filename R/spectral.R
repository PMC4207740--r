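#' Power spectrum of one scoring epoch
#'
#' Welch-style estimate on the analysis grid: the epoch is split into
#' non-overlapping 2-s segments, each Hann-windowed and periodogram
#' transformed (native 0.5 Hz spacing), and the segment periodograms are
#' averaged. Only the 0.5-20 Hz bins are retained unless `full_band = TRUE`.
#' A 4-s epoch natively yields 0.25 Hz spacing; `method = "fft4s"` instead
#' computes the single 4-s Hann periodogram and averages adjacent 0.25 Hz
#' bins onto the 0.5 Hz grid.
#'
#' Power is one-sided spectral density in (signal units)^2 / Hz: for a
#' full-band spectrum, `sum(power) * 0.5` equals the Hann-windowed signal's
#' mean square divided by the window's mean-square power correction
#' (Parseval).
#'
#' @param x Numeric vector of exactly `epoch_seconds * sampling_rate` finite
#'   samples.
#' @param sampling_rate Sampling rate in Hz.
#' @param epoch_seconds Epoch length in seconds.
#' @param method `"welch"` (default, two 2-s Hann segments) or `"fft4s"`
#'   (4-s periodogram, adjacent-bin averaging).
#' @param full_band Keep the whole 0 to Nyquist grid instead of 0.5-20 Hz.
#' @return A tibble of class `power_spectrum` with columns `frequency`, `power`
#'   and attributes `n_epochs_averaged`, `sampling_rate`.
#' @examples
#' t <- seq(0, 4, length.out = 1025)[-1025]
#' sp <- epoch_spectrum(sin(2 * pi * 8 * t))
#' sp$frequency[which.max(sp$power)]
#' @export
epoch_spectrum <- function(x, sampling_rate = 256, epoch_seconds = 4,
                           method = c("welch", "fft4s"), full_band = FALSE) {
  method <- match.arg(method)
  spe <- as.integer(sampling_rate * epoch_seconds)
  if (length(x) != spe) {
    abort(paste0("Epoch must contain exactly ", spe, " samples, got ", length(x), "."))
  }
  if (!all(is.finite(x))) abort("Epoch contains non-finite samples.")
  p <- psd_epochs(matrix(x, ncol = 1), sampling_rate, epoch_seconds,
    method = method, full_band = full_band
  )
  new_power_spectrum(p$frequency, p$power[, 1],
    n_epochs_averaged = 1L,
    sampling_rate = sampling_rate
  )
}

new_power_spectrum <- function(frequency, power, n_epochs_averaged = 1L,
                               state = NA_character_, sampling_rate = 256) {
  structure(
    tibble::tibble(frequency = frequency, power = power),
    n_epochs_averaged = n_epochs_averaged,
    state = state,
    sampling_rate = sampling_rate,
    class = c("power_spectrum", class(tibble::tibble()))
  )
}

# Periodogram machinery shared by all spectral operations. `mat` is one
# column per epoch; returns list(frequency, power) with power one column per
# epoch (density, (units)^2/Hz).
psd_epochs <- function(mat, fs, epoch_seconds, method = "welch",
                       full_band = FALSE) {
  spe <- nrow(mat)
  if (method == "welch") {
    seg <- as.integer(2 * fs)
    nseg <- spe %/% seg
    if (nseg < 1) abort("Epoch shorter than one 2-s Welch segment.")
    segmat <- matrix(mat[seq_len(nseg * seg), , drop = FALSE], nrow = seg)
  } else {
    seg <- spe
    nseg <- 1L
    segmat <- mat
  }
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(seg) - 1) / seg))
  U <- sum(w^2)
  X <- stats::mvfft(segmat * w)
  half <- seg %/% 2
  pw <- (Mod(X[seq_len(half + 1), , drop = FALSE])^2) / (fs * U)
  pw[2:half, ] <- 2 * pw[2:half, , drop = FALSE]
  if (nseg > 1) { # average the segments belonging to one epoch
    m <- ncol(mat)
    dim(pw) <- c(half + 1, nseg, m)
    pw <- colMeans(aperm(pw, c(2, 1, 3)))
    dim(pw) <- c(half + 1, m)
  }
  freq <- (0:half) * fs / seg
  if (method == "fft4s" && !full_band) {
    # fold native 0.25 Hz bins onto the 0.5 Hz grid by adjacent-bin averaging
    grid <- seq(0.5, 20, by = 0.5)
    idx1 <- match(grid - fs / seg, freq)
    idx2 <- match(grid, freq)
    pw <- (pw[idx1, , drop = FALSE] + pw[idx2, , drop = FALSE]) / 2
    return(list(frequency = grid, power = pw))
  }
  if (!full_band) {
    keep <- which(freq >= 0.5 - 1e-9 & freq <= 20 + 1e-9)
    freq <- freq[keep]
    pw <- pw[keep, , drop = FALSE]
  }
  list(frequency = freq, power = pw)
}

# Spectra for selected epochs of a recording, chunked to bound memory.
recording_epoch_psd <- function(recording, epochs, channel = "EEG",
                                method = "welch", chunk = 2048L) {
  spe <- as.integer(recording$sampling_rate * recording$epoch_seconds)
  sig <- recording$channels[[channel]]
  if (is.null(sig)) abort(paste0("Recording has no channel '", channel, "'."))
  nb <- length(seq(0.5, 20, by = 0.5))
  out <- matrix(NA_real_, nb, length(epochs))
  freq <- NULL
  for (start in seq(1, length(epochs), by = chunk)) {
    idx <- epochs[start:min(start + chunk - 1L, length(epochs))]
    cols <- vapply(idx, function(e) sig[((e - 1) * spe + 1):(e * spe)],
      numeric(spe)
    )
    p <- psd_epochs(matrix(cols, nrow = spe), recording$sampling_rate,
      recording$epoch_seconds,
      method = method
    )
    freq <- p$frequency
    out[, start:(start + length(idx) - 1L)] <- p$power
  }
  list(frequency = freq, power = out)
}

#' Mean power over a frequency band
#'
#' Arithmetic mean of the spectrum over grid bins with `lo <= f <= hi`, both
#' ends inclusive. Slow-wave activity (SWA) is `band_power(sp, 0.5, 4)`
#' (8 bins on the 0.5 Hz grid).
#'
#' @param spectrum A [epoch_spectrum()] result (or any tibble with
#'   `frequency` and `power` columns).
#' @param lo,hi Band edges in Hz, inside the spectrum's grid.
#' @return Scalar mean power.
#' @export
band_power <- function(spectrum, lo, hi) {
  if (lo >= hi) abort("`lo` must be below `hi`.")
  rng <- range(spectrum$frequency)
  if (lo < rng[1] - 1e-9 || hi > rng[2] + 1e-9) {
    abort(paste0(
      "Band [", lo, ", ", hi, "] lies outside the spectrum grid [",
      rng[1], ", ", rng[2], "]."
    ))
  }
  sel <- spectrum$frequency >= lo - 1e-9 & spectrum$frequency <= hi + 1e-9
  mean(spectrum$power[sel])
}

# Per-epoch SWA (0.5-4 Hz mean power) for the given epoch indices.
swa_per_epoch <- function(recording, epochs, method = "welch") {
  p <- recording_epoch_psd(recording, epochs, method = method)
  sel <- p$frequency >= 0.5 - 1e-9 & p$frequency <= 4 + 1e-9
  colMeans(p$power[sel, , drop = FALSE])
}

#' Individual SWA reference from the baseline light period
#'
#' Mean SWA over the chronologically last `n_epochs` artifact-free NREM
#' epochs of the baseline light period (ZT0-12 of `baseline_day`). Used to
#' express all SWA measures of an animal as a percentage of its own baseline,
#' correcting for absolute-power differences between individuals.
#'
#' @param recording An [epoched_recording()].
#' @param hyp The matching [hypnogram()].
#' @param baseline_day Which recording day is the baseline (1-based).
#' @param n_epochs Reference window length; lowering it below the standard
#'   900 epochs is allowed but logged.
#' @param method Periodogram method, see [epoch_spectrum()].
#' @return Scalar reference SWA (raw power units).
#' @export
swa_reference <- function(recording, hyp, baseline_day = 1, n_epochs = 900,
                          method = "welch") {
  hyp <- as_hypnogram(hyp)
  if (n_epochs < 900) {
    inform(paste0("SWA reference window reduced to ", n_epochs, " epochs."))
  }
  light_lo <- (baseline_day - 1) * hyp_schedule(hyp)$cycle_hours
  light_hi <- light_lo + hyp_schedule(hyp)$light_hours
  ok <- which(hyp$state == "NREM" & !hyp$artifact &
    hyp$zt >= light_lo & hyp$zt < light_hi)
  if (length(ok) < n_epochs) {
    abort(paste0(
      "Only ", length(ok), " artifact-free NREM epochs in the baseline light ",
      "period; ", n_epochs, " required."
    ))
  }
  ref_epochs <- tail(ok, n_epochs)
  mean(swa_per_epoch(recording, ref_epochs, method = method))
}

#' Normalized SWA time course
#'
#' Per time bin, the mean SWA over artifact-free NREM epochs expressed as a
#' percentage of `reference`. Bins with fewer than `min_epochs` qualifying
#' epochs are flagged missing (`NA`, not zero).
#'
#' @inheritParams swa_reference
#' @param reference Scalar reference SWA (> 0), e.g. from [swa_reference()].
#' @param bin_hours Bin width in hours.
#' @param min_epochs Minimum artifact-free NREM epochs per bin.
#' @return A tibble with one row per bin: `day`, `zt_start` (wrapped to the
#'   24-h cycle), `bin_start` (recording hours), `swa_pct`, `n_nrem_epochs`,
#'   `missing`.
#' @export
swa_timecourse <- function(recording, hyp, reference, bin_hours = 2,
                           min_epochs = 10, method = "welch") {
  hyp <- as_hypnogram(hyp)
  if (!is.numeric(reference) || reference <= 0) {
    abort("`reference` must be a positive scalar.")
  }
  span <- hyp_span_hours(hyp)
  n_bins <- ceiling(span / bin_hours - 1e-9)
  ok <- which(hyp$state == "NREM" & !hyp$artifact)
  swa <- rep(NA_real_, length(ok))
  if (length(ok) > 0) swa <- swa_per_epoch(recording, ok, method = method)
  bin_of <- pmin(floor((hyp$zt[ok] - hyp_start_zt(hyp)) / bin_hours), n_bins - 1) + 1
  agg_n <- tabulate(bin_of, nbins = n_bins)
  agg_sum <- vapply(
    seq_len(n_bins),
    function(b) sum(swa[bin_of == b]), numeric(1)
  )
  cycle <- hyp_schedule(hyp)$cycle_hours
  bin_start <- hyp_start_zt(hyp) + (seq_len(n_bins) - 1) * bin_hours
  tibble::tibble(
    day = floor(bin_start / cycle) + 1,
    zt_start = bin_start %% cycle,
    bin_start = bin_start,
    n_nrem_epochs = agg_n,
    swa_pct = ifelse(agg_n >= min_epochs, agg_sum / agg_n / reference * 100, NA_real_),
    missing = agg_n < min_epochs
  )
}

#' Mean spectrum of one vigilance state over an interval
#'
#' Bin-wise mean of the per-epoch spectra of all artifact-free epochs of the
#' requested state whose start falls in `interval` (recording hours,
#' half-open).
#'
#' @inheritParams swa_reference
#' @param state `"WAKE"`, `"NREM"` or `"REM"`.
#' @param interval Length-2 numeric interval in recording hours; `NULL` means
#'   the whole recording.
#' @return A `power_spectrum` tibble; the number of epochs averaged is stored
#'   in the `n_epochs_averaged` attribute.
#' @export
mean_state_spectrum <- function(recording, hyp, state, interval = NULL,
                                method = "welch") {
  hyp <- as_hypnogram(hyp)
  stopifnot(state %in% VIGILANCE_STATES)
  interval <- interval %||% c(hyp_start_zt(hyp), hyp_start_zt(hyp) + hyp_span_hours(hyp))
  ok <- which(hyp$state == state & !hyp$artifact &
    hyp$zt >= interval[1] & hyp$zt < interval[2])
  if (length(ok) == 0) {
    abort(paste0(
      "No artifact-free ", state, " epochs in interval [",
      interval[1], ", ", interval[2], ") h."
    ))
  }
  p <- recording_epoch_psd(recording, ok, method = method)
  new_power_spectrum(p$frequency, rowMeans(p$power),
    n_epochs_averaged = length(ok), state = state,
    sampling_rate = recording$sampling_rate
  )
}

#' Theta peak frequency of a mean REM spectrum
#'
#' The grid frequency carrying maximal power among the 5-10 Hz bins (both
#' ends inclusive, 11 bins on the 0.5 Hz grid); ties are broken toward the
#' lowest frequency.
#'
#' @param spectrum A `power_spectrum` (typically from [mean_state_spectrum()]
#'   on REM epochs).
#' @param range Search band in Hz.
#' @return A one-row tibble: `tpf` (Hz), `n_epochs`.
#' @export
theta_peak_frequency <- function(spectrum, range = c(5, 10)) {
  sel <- which(spectrum$frequency >= range[1] - 1e-9 &
    spectrum$frequency <= range[2] + 1e-9)
  if (length(sel) == 0) abort("Spectrum does not cover the theta search band.")
  pw <- spectrum$power[sel]
  if (all(pw == 0)) abort("All-zero power in the theta search band.")
  tibble::tibble(
    tpf = spectrum$frequency[sel[which.max(pw)]],
    n_epochs = attr(spectrum, "n_epochs_averaged") %||% NA_integer_
  )
}
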