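#' Per-minute wheel-count series
#'
#' @param counts Non-negative integer counts, one per minute.
#' @param start_zt ZT hour of the first minute.
#' @param schedule A [light_schedule()].
#' @return A tibble of class `activity_series` with columns `minute`
#'   (0-based), `zt` (hours, not wrapped) and `count`.
#' @export
activity_series <- function(counts, start_zt = 0, schedule = light_schedule()) {
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Wheel counts must be non-negative integers.")
  }
  n <- length(counts)
  structure(
    tibble::tibble(
      minute = seq_len(n) - 1L,
      zt = start_zt + (seq_len(n) - 1) / 60,
      count = as.integer(counts)
    ),
    start_zt = start_zt,
    schedule = schedule,
    class = c("activity_series", class(tibble::tibble()))
  )
}

#' Simulate voluntary wheel running
#'
#' Per-minute counts are Poisson with rate `wheel_rate_light` during the light
#' phase and the group's `wheel_rate_dark` during the dark phase — nocturnal
#' activity with a group-dependent level.
#'
#' @param config A [sim_config()].
#' @param group Group label selecting the dark-phase rate.
#' @param seed Integer seed.
#' @param n_days Number of recorded days.
#' @return An [activity_series()].
#' @examples
#' s <- simulate_wheel_activity(sim_config(), "WT", seed = 1, n_days = 2)
#' sum(s$count)
#' @export
simulate_wheel_activity <- function(config, group = "WT", seed = 1, n_days = 5) {
  stopifnot(inherits(config, "sim_config"))
  rate_l <- config$wheel_rate_light
  rate_d <- group_param(config$wheel_rate_dark, group, "wheel_rate_dark")
  if (rate_l < 0 || rate_d < 0) abort("Wheel rates must be non-negative.")
  n <- as.integer(n_days * 24 * 60)
  zt <- (seq_len(n) - 1) / 60
  rate <- ifelse(in_light_phase(zt, config$schedule), rate_l, rate_d)
  with_rng(seed, {
    activity_series(rpois(n, rate), start_zt = 0, schedule = config$schedule)
  })
}

#' Fold wheel counts onto one 24-h activity profile
#'
#' Counts are summed within bins of `bin_minutes` and accumulated across all
#' recorded days onto a single ZT 0-24 cycle (the standard actogram-style
#' activity profile).
#'
#' @param series An [activity_series()] covering at least one full day.
#' @param bin_minutes Bin width in minutes; must divide 1440.
#' @return A tibble of class `activity_profile` with `bin`, `zt_start` and
#'   accumulated `count` per bin.
#' @export
bin_activity <- function(series, bin_minutes = 18) {
  if (1440 %% bin_minutes != 0) abort("`bin_minutes` must divide 1440.")
  if (nrow(series) < 1440) abort("Series must cover at least one full day.")
  start_zt <- attr(series, "start_zt") %||% 0
  zt_min <- (start_zt * 60 + series$minute) %% 1440
  bin <- floor(zt_min / bin_minutes) + 1
  n_bins <- 1440 %/% bin_minutes
  counts <- vapply(seq_len(n_bins), function(b) sum(series$count[bin == b]), numeric(1))
  structure(
    tibble::tibble(
      bin = seq_len(n_bins),
      zt_start = (seq_len(n_bins) - 1) * bin_minutes / 60,
      count = counts
    ),
    bin_minutes = bin_minutes,
    schedule = attr(series, "schedule") %||% light_schedule(),
    class = c("activity_profile", class(tibble::tibble()))
  )
}

#' ZT time of half-maximal nocturnal activity
#'
#' After smoothing the folded profile with a centered circular moving average,
#' finds the nocturnal (dark-phase) peak and returns the linearly interpolated
#' ZT hour, after the peak, at which activity first falls below 50% of that
#' peak. A profile that never falls below half-max before lights-on raises a
#' condition of class `chronosleep_no_crossing`.
#'
#' @param profile An [bin_activity()] result.
#' @param smoothing_bins Width of the centered moving average (odd count;
#'   1 disables smoothing).
#' @return Scalar ZT hour of the half-max crossing.
#' @examples
#' prof <- bin_activity(activity_series(
#'   rep(c(0, 100, 0), c(12 * 60, 6 * 60, 6 * 60))
#' ))
#' half_max_activity_time(prof)
#' @export
half_max_activity_time <- function(profile, smoothing_bins = 3) {
  if (smoothing_bins %% 2 != 1 || smoothing_bins < 1) {
    abort("`smoothing_bins` must be a positive odd count.")
  }
  v <- profile$count
  n <- length(v)
  if (smoothing_bins > 1) {
    k <- (smoothing_bins - 1) / 2
    padded <- c(tail(v, k), v, head(v, k)) # circular: the profile is a 24-h fold
    v <- as.numeric(stats::filter(padded, rep(1 / smoothing_bins, smoothing_bins)))
    v <- v[(k + 1):(k + n)]
  }
  bin_minutes <- attr(profile, "bin_minutes") %||%
    ((profile$zt_start[2] - profile$zt_start[1]) * 60)
  centers <- profile$zt_start + bin_minutes / 120
  sched <- attr(profile, "schedule") %||% light_schedule()
  dark <- !in_light_phase(centers, sched)
  if (!any(dark) || max(v[dark]) <= 0) {
    abort("Profile has no positive nocturnal activity.")
  }
  dark_idx <- which(dark)
  peak_i <- dark_idx[which.max(v[dark_idx])]
  half <- v[peak_i] / 2
  scan <- dark_idx[dark_idx > peak_i]
  prev <- peak_i
  for (i in scan) {
    if (v[i] < half) {
      t <- centers[prev] +
        (centers[i] - centers[prev]) * (v[prev] - half) / (v[prev] - v[i])
      return(t)
    }
    prev <- i
  }
  abort("Activity never falls below half-max before lights-on.",
    class = "chronosleep_no_crossing"
  )
}
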