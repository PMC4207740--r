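#' Build a hypnogram from per-epoch state labels
#'
#' A hypnogram is the backbone of all sleep-architecture metrics: one vigilance
#' state per scoring epoch plus an artifact flag. Artifact-flagged epochs keep
#' their state label (they count toward time budgets) and are excluded only
#' from spectral averaging.
#'
#' @param states Character vector over `"WAKE"`, `"NREM"`, `"REM"`.
#' @param artifact Logical vector, one flag per epoch (default all `FALSE`).
#' @param epoch_seconds Epoch length in seconds.
#' @param start_zt ZT hour of the first epoch's start.
#' @param schedule A [light_schedule()].
#' @return A tibble of class `hypnogram` with columns `epoch` (1-based index),
#'   `zt` (ZT hour of epoch start, not wrapped at 24), `state`, `artifact`.
#' @examples
#' hyp <- hypnogram(rep(c("WAKE", "NREM"), each = 3))
#' hyp
#' @export
hypnogram <- function(states, artifact = NULL, epoch_seconds = 4,
                      start_zt = 0, schedule = light_schedule()) {
  states <- as.character(states)
  if (length(states) > 0 && !all(states %in% VIGILANCE_STATES)) {
    bad <- setdiff(unique(states), VIGILANCE_STATES)
    abort(paste0("Unknown vigilance state(s): ", paste(bad, collapse = ", ")))
  }
  artifact <- artifact %||% rep(FALSE, length(states))
  if (length(artifact) != length(states)) {
    abort("`states` and `artifact` must have equal length.")
  }
  n <- length(states)
  out <- tibble::tibble(
    epoch = seq_len(n),
    zt = start_zt + (seq_len(n) - 1) * epoch_seconds / 3600,
    state = states,
    artifact = as.logical(artifact)
  )
  new_hypnogram(out, epoch_seconds, start_zt, schedule)
}

new_hypnogram <- function(df, epoch_seconds, start_zt, schedule) {
  structure(
    df,
    epoch_seconds = epoch_seconds,
    start_zt = start_zt,
    schedule = schedule,
    class = c("hypnogram", class(tibble::tibble()))
  )
}

#' Coerce a data frame to a hypnogram
#'
#' @param x Data frame with at least `state` and optionally `artifact` columns.
#' @inheritParams hypnogram
#' @return A `hypnogram` tibble.
#' @export
as_hypnogram <- function(x, epoch_seconds = 4, start_zt = 0,
                         schedule = light_schedule()) {
  if (inherits(x, "hypnogram")) {
    return(x)
  }
  hypnogram(x$state,
    artifact = x$artifact %||% rep(FALSE, nrow(x)),
    epoch_seconds = epoch_seconds, start_zt = start_zt, schedule = schedule
  )
}

epoch_seconds <- function(hyp) attr(hyp, "epoch_seconds") %||% 4
hyp_schedule <- function(hyp) attr(hyp, "schedule") %||% light_schedule()
hyp_start_zt <- function(hyp) attr(hyp, "start_zt") %||% 0

# Recording span in hours.
hyp_span_hours <- function(hyp) nrow(hyp) * epoch_seconds(hyp) / 3600

#' Simulate a hypnogram as a diurnally modulated Markov chain
#'
#' States evolve as a first-order Markov chain over WAKE/NREM/REM whose
#' transitions into sleep states are multiplied, at epoch time t (ZT hours),
#' by `m(t) = 1 + A * cos(2*pi*(t - phase)/24)` with the rows renormalized.
#' With phase at ZT6, sleep propensity peaks mid-light, producing the diurnal
#' sleep-wake distribution whose depth A differs between groups. Artifact
#' flags are drawn independently per epoch.
#'
#' @param config A [sim_config()].
#' @param group Group label (must index the per-group config parameters).
#' @param seed Integer seed; output is deterministic given (config, group, seed).
#' @param n_epochs Number of epochs; default spans `recording_days` whole days.
#' @param initial_state State of epoch 1.
#' @return A [hypnogram()] tibble.
#' @examples
#' cfg <- sim_config(recording_days = 1)
#' hyp <- simulate_hypnogram(cfg, "WT", seed = 1)
#' table(hyp$state)
#' @export
simulate_hypnogram <- function(config, group = "WT", seed = 1,
                               n_epochs = NULL, initial_state = "WAKE") {
  stopifnot(inherits(config, "sim_config"))
  eps <- config$epoch_seconds
  n <- n_epochs %||% as.integer(round(config$recording_days * 24 * 3600 / eps))
  A <- group_param(config$diurnal_modulation_depth, group, "diurnal_modulation_depth")
  phase <- config$modulation_phase
  P <- config$base_transition_matrix
  cycle <- config$schedule$cycle_hours

  zt_mid <- (seq_len(n) - 0.5) * eps / 3600
  m <- 1 + A * cos(2 * pi * (zt_mid - phase) / cycle)

  # Off-diagonal entries into sleep states get the modulation factor.
  sleep_cols <- match(c("NREM", "REM"), VIGILANCE_STATES)
  mod_mask <- matrix(FALSE, 3, 3)
  mod_mask[, sleep_cols] <- TRUE
  diag(mod_mask) <- FALSE

  worst <- max(m)
  if (any(P[mod_mask] * worst > 1)) {
    at <- which.max(m)
    abort(paste0(
      "Modulated transition probability exceeds 1 at epoch ", at,
      " (m = ", signif(worst, 4), "); reduce the modulation depth."
    ))
  }

  states <- integer(n)
  with_rng(seed, {
    u <- runif(n)
    art <- runif(n) < config$artifact_probability
    cur <- match(initial_state, VIGILANCE_STATES)
    if (is.na(cur)) abort("`initial_state` must be WAKE, NREM or REM.")
    states[1] <- cur
    for (t in seq_len(n - 1L)) {
      row <- P[cur, ]
      scale_idx <- mod_mask[cur, ]
      row[scale_idx] <- row[scale_idx] * m[t]
      row <- row / sum(row)
      cum <- cumsum(row)
      cur <- 1L + sum(u[t] > cum)
      states[t + 1L] <- cur
    }
    hypnogram(VIGILANCE_STATES[states],
      artifact = art, epoch_seconds = eps,
      start_zt = 0, schedule = config$schedule
    )
  })
}

#' Enforce wakefulness inside a ZT window (sleep deprivation)
#'
#' Emulates sleep deprivation by gentle handling: each epoch inside the window
#' is independently forced to WAKE with probability `efficiency`; epochs
#' outside the window are untouched. The window is given in recording hours
#' (not wrapped), so deprivation on day 2 of a 2-day recording under the
#' default ZT0-6 protocol uses `window = c(24, 30)`.
#'
#' @param hyp A [hypnogram()].
#' @param window Length-2 numeric, recording-hours interval `[start, end)`.
#' @param efficiency Per-epoch probability of enforcement, in `[0, 1]`.
#' @param seed Integer seed.
#' @return The modified hypnogram.
#' @examples
#' cfg <- sim_config(recording_days = 1)
#' hyp <- simulate_hypnogram(cfg, "WT", seed = 1)
#' sd_hyp <- apply_sleep_deprivation(hyp, c(0, 6), 0.97, seed = 2)
#' mean(sd_hyp$state[sd_hyp$zt < 6] == "WAKE")
#' @export
apply_sleep_deprivation <- function(hyp, window, efficiency, seed = 1) {
  hyp <- as_hypnogram(hyp)
  if (efficiency < 0 || efficiency > 1) abort("`efficiency` must lie in [0, 1].")
  if (length(window) != 2 || diff(window) <= 0) {
    abort("`window` must be an increasing interval c(start, end).")
  }
  span <- c(hyp_start_zt(hyp), hyp_start_zt(hyp) + hyp_span_hours(hyp))
  if (window[1] < span[1] || window[2] > span[2] + 1e-9) {
    abort("`window` must lie inside the recording span.")
  }
  idx <- which(hyp$zt >= window[1] & hyp$zt < window[2])
  if (length(idx) == 0) {
    return(hyp)
  }
  with_rng(seed, {
    force_wake <- runif(length(idx)) < efficiency
    hyp$state[idx[force_wake]] <- "WAKE"
  })
  hyp
}

#' Two-process homeostat trajectory (Process S)
#'
#' The latent sleep-pressure variable S rises saturating during WAKE and REM,
#' `S <- min(1, S + dt / tau_rise)`, and decays exponentially during NREM,
#' `S <- S * exp(-dt / tau_decay)`, with dt the epoch length. Slow-wave
#' activity synthesis scales NREM delta amplitude affinely in S, so enforced
#' wakefulness produces the classic SWA rebound.
#'
#' @param hyp A [hypnogram()].
#' @param tau_rise,tau_decay Time constants in hours.
#' @param s0 Initial value of S in `[0, 1]`.
#' @return Numeric vector: S at the *start* of each epoch (`s0` first).
#' @examples
#' hyp <- hypnogram(rep(c("WAKE", "NREM"), each = 900))
#' s <- homeostat_trajectory(hyp)
#' plot(hyp$zt, s, type = "l", xlab = "ZT (h)", ylab = "S")
#' @export
homeostat_trajectory <- function(hyp, tau_rise = 18, tau_decay = 4, s0 = 0.5) {
  hyp <- as_hypnogram(hyp)
  n <- nrow(hyp)
  if (n == 0) {
    return(numeric(0))
  }
  dt <- epoch_seconds(hyp) / 3600
  rise <- dt / tau_rise
  decay <- exp(-dt / tau_decay)
  is_nrem <- hyp$state == "NREM"
  s <- numeric(n)
  cur <- s0
  for (t in seq_len(n)) {
    s[t] <- cur
    cur <- if (is_nrem[t]) cur * decay else min(1, cur + rise)
  }
  s
}
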