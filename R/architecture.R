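#' Vigilance-state time budgets per bin, phase and day
#'
#' Computes each state's percentage of recording time in consecutive bins of
#' `bin_hours`, plus 12-h light (L) / dark (D) aggregates and the 24-h total
#' (phases pooled over all recorded days). Artifact-flagged epochs count
#' toward their state's time budget — the artifact flag only excludes epochs
#' from spectral averaging.
#'
#' @param hyp A [hypnogram()].
#' @param bin_hours Bin width in hours; must divide the recording span.
#' @param animal_id,group Optional labels carried into the output.
#' @return A tibble of class `vigilance_summary` with columns `scope`
#'   (`"bin"`, `"phase"` or `"total"`), `label`, `zt_start` (bins only),
#'   `state`, `pct`, `n_epochs` (total epochs of the bin/phase).
#' @examples
#' hyp <- hypnogram(rep(c("WAKE", "NREM", "REM"), each = 600))
#' state_fractions(hyp, bin_hours = 2)
#' @export
state_fractions <- function(hyp, bin_hours = 2, animal_id = NA_character_,
                            group = NA_character_) {
  hyp <- as_hypnogram(hyp)
  if (nrow(hyp) == 0) abort("Hypnogram is empty.")
  span <- hyp_span_hours(hyp)
  eph <- 3600 / epoch_seconds(hyp) # epochs per hour
  if (abs(span / bin_hours - round(span / bin_hours)) > 1e-9) {
    abort("`bin_hours` must divide the recording span.")
  }
  n_bins <- as.integer(round(span / bin_hours))
  rel <- hyp$zt - hyp_start_zt(hyp)
  bin <- pmin(floor(rel / bin_hours), n_bins - 1) + 1

  pct_table <- function(states, total) {
    counts <- vapply(VIGILANCE_STATES, function(s) sum(states == s), numeric(1))
    tibble::tibble(
      state = VIGILANCE_STATES,
      pct = unname(counts) / total * 100,
      n_epochs = total
    )
  }

  bins <- purrr::map_dfr(seq_len(n_bins), function(b) {
    idx <- bin == b
    if (!any(idx)) abort(paste0("Bin ", b, " contains no epochs."))
    zt0 <- hyp_start_zt(hyp) + (b - 1) * bin_hours
    dplyr::mutate(pct_table(hyp$state[idx], sum(idx)),
      scope = "bin",
      label = paste0("ZT", zt0 %% 24, "-", (zt0 + bin_hours - 1e-9) %% 24 + 1e-9),
      zt_start = zt0, .before = 1
    )
  })

  sched <- hyp_schedule(hyp)
  light <- in_light_phase(hyp$zt, sched)
  phases <- dplyr::bind_rows(
    dplyr::mutate(pct_table(hyp$state[light], sum(light)),
      scope = "phase", label = "L", zt_start = NA_real_, .before = 1
    ),
    dplyr::mutate(pct_table(hyp$state[!light], sum(!light)),
      scope = "phase", label = "D", zt_start = NA_real_, .before = 1
    )
  )
  total <- dplyr::mutate(pct_table(hyp$state, nrow(hyp)),
    scope = "total", label = "24h", zt_start = NA_real_, .before = 1
  )

  out <- dplyr::bind_rows(bins, phases, total)
  out$animal_id <- animal_id
  out$group <- group
  structure(out,
    bin_hours = bin_hours,
    class = c("vigilance_summary", class(tibble::tibble()))
  )
}

#' Light-dark amplitude of each vigilance state
#'
#' Quantifies the diurnal sleep-wake distribution as, per state, the signed
#' difference between its percentage of time in the light and in the dark
#' phase. Because the commonly reported "relative L-D difference" admits a
#' normalized reading, `normalized = TRUE` instead returns
#' `(L - D) / ((L + D) / 2)`; the signed difference in percentage points is
#' the default.
#'
#' @param summary A [state_fractions()] result containing the phase
#'   aggregates.
#' @param normalized Use the normalized variant.
#' @return A tibble with columns `state`, `amplitude` (plus `animal_id`,
#'   `group` if present in `summary`).
#' @export
ld_amplitude <- function(summary, normalized = FALSE) {
  ph <- dplyr::filter(summary, .data$scope == "phase")
  if (!all(c("L", "D") %in% ph$label)) {
    abort("`summary` lacks the L and D phase aggregates.")
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(ph, "label", "state", "pct"),
    names_from = "label", values_from = "pct"
  )
  amp <- if (normalized) {
    (wide$L - wide$D) / ((wide$L + wide$D) / 2)
  } else {
    wide$L - wide$D
  }
  out <- tibble::tibble(state = wide$state, amplitude = amp)
  if ("animal_id" %in% names(summary)) out$animal_id <- summary$animal_id[1]
  if ("group" %in% names(summary)) out$group <- summary$group[1]
  out
}

#' Fraction of wakefulness per short bin (raster trace)
#'
#' @param hyp A [hypnogram()].
#' @param bin_minutes Bin width; must be an integer number of epochs and
#'   divide the recording span.
#' @return A tibble with `bin`, `zt_start` and `frac_wake` in `[0, 1]`.
#' @export
wake_raster <- function(hyp, bin_minutes = 5) {
  hyp <- as_hypnogram(hyp)
  eps <- epoch_seconds(hyp)
  per_bin <- bin_minutes * 60 / eps
  if (abs(per_bin - round(per_bin)) > 1e-9) {
    abort("`bin_minutes` must correspond to an integer number of epochs.")
  }
  per_bin <- as.integer(round(per_bin))
  if (nrow(hyp) %% per_bin != 0) {
    abort("`bin_minutes` must divide the recording span.")
  }
  n_bins <- nrow(hyp) %/% per_bin
  wake <- hyp$state == "WAKE"
  frac <- colMeans(matrix(wake, nrow = per_bin))
  tibble::tibble(
    bin = seq_len(n_bins),
    zt_start = hyp_start_zt(hyp) + (seq_len(n_bins) - 1) * bin_minutes / 60,
    frac_wake = frac
  )
}

#' Sleep-deprivation efficiency
#'
#' Percentage of epochs scored WAKE inside a window of recording hours —
#' the standard report of how complete an enforced-wakefulness protocol was.
#'
#' @param hyp A [hypnogram()].
#' @param window Length-2 numeric interval `[start, end)` in recording hours.
#' @return Scalar percentage in `[0, 100]`.
#' @export
sd_efficiency <- function(hyp, window) {
  hyp <- as_hypnogram(hyp)
  span <- c(hyp_start_zt(hyp), hyp_start_zt(hyp) + hyp_span_hours(hyp))
  if (window[1] < span[1] - 1e-9 || window[2] > span[2] + 1e-9) {
    abort("`window` must lie inside the recording span.")
  }
  idx <- hyp$zt >= window[1] & hyp$zt < window[2]
  if (!any(idx)) abort("`window` contains no epochs.")
  mean(hyp$state[idx] == "WAKE") * 100
}
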