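# Shaded dark-phase rectangles for ZT-axis plots.
dark_phase_layer <- function(span_hours, schedule = light_schedule()) {
  starts <- seq(schedule$light_hours, span_hours, by = schedule$cycle_hours)
  shades <- tibble::tibble(
    xmin = starts,
    xmax = pmin(starts + schedule$dark_hours, span_hours)
  )
  ggplot2::geom_rect(
    data = shades,
    ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax, ymin = -Inf, ymax = Inf),
    inherit.aes = FALSE, fill = "grey85", alpha = 0.5
  )
}

#' Plot a vigilance-state time course
#'
#' @param object A [state_fractions()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vigilance_summary <- function(object, ...) {
  bins <- dplyr::filter(tibble::as_tibble(object), .data$scope == "bin")
  span <- max(bins$zt_start) + (attr(object, "bin_hours") %||% 2)
  ggplot2::ggplot(bins, ggplot2::aes(
    .data$zt_start, .data$pct,
    colour = .data$state
  )) +
    dark_phase_layer(span) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(
      x = "Zeitgeber time (h)", y = "% recording time",
      colour = "State"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a power spectrum
#'
#' @param object A `power_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.power_spectrum <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(.data$frequency, .data$power)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Frequency (Hz)", y = expression(Power ~ (units^2 / Hz)),
      title = if (!is.na(attr(object, "state"))) {
        paste0(
          attr(object, "state"), " mean spectrum (n = ",
          attr(object, "n_epochs_averaged"), " epochs)"
        )
      }
    ) +
    ggplot2::theme_minimal()
}

#' Plot a folded wheel-activity profile
#'
#' @param object An [bin_activity()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.activity_profile <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(.data$zt_start, .data$count)
  ) +
    dark_phase_layer(24, attr(object, "schedule") %||% light_schedule()) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Accumulated counts / bin") +
    ggplot2::theme_minimal()
}

#' Wake raster plot for a hypnogram
#'
#' Fraction of wakefulness per short bin, the single-animal trace used to
#' visualize the diurnal sleep-wake distribution.
#'
#' @param hyp A [hypnogram()].
#' @param bin_minutes Bin width in minutes.
#' @return A ggplot.
#' @export
plot_wake_raster <- function(hyp, bin_minutes = 5) {
  r <- wake_raster(hyp, bin_minutes)
  ggplot2::ggplot(r, ggplot2::aes(.data$zt_start, .data$frac_wake)) +
    dark_phase_layer(max(r$zt_start) + bin_minutes / 60, hyp_schedule(hyp)) +
    ggplot2::geom_col(width = bin_minutes / 60, fill = "black") +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "Fraction wake") +
    ggplot2::theme_minimal()
}

#' Plot a normalized SWA time course
#'
#' @param timecourse A [swa_timecourse()] result.
#' @return A ggplot.
#' @export
plot_swa_timecourse <- function(timecourse) {
  ggplot2::ggplot(timecourse, ggplot2::aes(.data$bin_start, .data$swa_pct)) +
    dark_phase_layer(max(timecourse$bin_start, na.rm = TRUE) + 2) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Recording time (h)", y = "SWA (% of baseline reference)") +
    ggplot2::theme_minimal()
}
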