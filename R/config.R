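#' Simulation configuration for synthetic sleep cohorts
#'
#' Collects every tunable of the cohort generator: hypnogram dynamics,
#' EEG/EMG synthesis, sleep-deprivation protocol, wheel running and the
#' planted day/night expression design. Group-resolved parameters
#' (`diurnal_modulation_depth`, `theta_center_frequency`, `wheel_rate_dark`)
#' are named numeric vectors; any group label used downstream must appear in
#' their names.
#'
#' Defaults emulate a two-genotype study: a "WT"-like group with a deep
#' diurnal modulation of sleep propensity and a "MUT"-like group in which the
#' modulation (and nocturnal wheel running) is attenuated while total sleep is
#' preserved.
#'
#' @param n_animals_per_group Animals simulated per group.
#' @param epoch_seconds Scoring epoch length in seconds.
#' @param sampling_rate EEG/EMG sampling rate in Hz.
#' @param recording_days Recorded days per animal (day 1 baseline; the sleep
#'   deprivation protocol, when applied, targets day 2).
#' @param base_transition_matrix 3x3 row-stochastic matrix over
#'   WAKE/NREM/REM; `WAKE -> REM` must be 0.
#' @param diurnal_modulation_depth Amplitude A of the multiplicative
#'   sleep-propensity modulation, per group (dimensionless, >= 0).
#' @param modulation_phase ZT hour at which sleep propensity peaks.
#' @param theta_center_frequency Center of the REM theta oscillation (Hz),
#'   per group.
#' @param theta_bandwidth Width of the REM theta band (Hz).
#' @param theta_gain,delta_gain,wake_gain Amplitude scalings (in units of the
#'   pink-noise floor's standard deviation) of the state-specific EEG
#'   components.
#' @param homeostat_enabled Couple NREM delta amplitude to the two-process
#'   homeostat state S (see [homeostat_trajectory()]).
#' @param homeostat_rise_tau,homeostat_decay_tau Time constants (hours) of the
#'   homeostat's rise during WAKE/REM and exponential decay during NREM.
#' @param artifact_probability Per-epoch probability of an artifact flag.
#' @param sd_window ZT interval (length-2 numeric) of enforced wakefulness.
#' @param sd_efficiency Probability that an epoch inside the window is forced
#'   to WAKE.
#' @param wheel_rate_light,wheel_rate_dark Poisson rates for wheel counts per
#'   minute; the dark rate is per group.
#' @param expression_n_genes,expression_n_planted Total and planted
#'   (day/night regulated) gene counts of the synthetic expression design.
#' @param expression_effect_log2fc Planted ZT16 - ZT4 effect in log2 units in
#'   the WT-like group.
#' @param expression_attenuation Factor scaling the planted effect in the
#'   mutant-like group.
#' @param expression_noise_sd Gaussian noise SD in log2 units.
#' @param expression_n_replicates Replicates per genotype x timepoint cell.
#' @param schedule A [light_schedule()].
#' @return A validated list of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_animals_per_group = 2, recording_days = 1)
#' cfg$base_transition_matrix
#' @export
sim_config <- function(n_animals_per_group = 8,
                       epoch_seconds = 4,
                       sampling_rate = 256,
                       recording_days = 2,
                       base_transition_matrix = default_transition_matrix(),
                       diurnal_modulation_depth = c(WT = 0.4, MUT = 0.15),
                       modulation_phase = 6,
                       theta_center_frequency = c(WT = 7.2, MUT = 7.6),
                       theta_bandwidth = 0.75,
                       theta_gain = 1.5,
                       delta_gain = 1.5,
                       wake_gain = 1,
                       homeostat_enabled = TRUE,
                       homeostat_rise_tau = 18,
                       homeostat_decay_tau = 4,
                       artifact_probability = 0.02,
                       sd_window = c(0, 6),
                       sd_efficiency = 0.97,
                       wheel_rate_light = 0.5,
                       wheel_rate_dark = c(WT = 12, MUT = 8),
                       expression_n_genes = 1000,
                       expression_n_planted = 20,
                       expression_effect_log2fc = 1.5,
                       expression_attenuation = 0.3,
                       expression_noise_sd = 0.25,
                       expression_n_replicates = 4,
                       schedule = light_schedule()) {
  cfg <- structure(
    list(
      n_animals_per_group = n_animals_per_group,
      epoch_seconds = epoch_seconds,
      sampling_rate = sampling_rate,
      recording_days = recording_days,
      base_transition_matrix = base_transition_matrix,
      diurnal_modulation_depth = diurnal_modulation_depth,
      modulation_phase = modulation_phase,
      theta_center_frequency = theta_center_frequency,
      theta_bandwidth = theta_bandwidth,
      theta_gain = theta_gain,
      delta_gain = delta_gain,
      wake_gain = wake_gain,
      homeostat_enabled = homeostat_enabled,
      homeostat_rise_tau = homeostat_rise_tau,
      homeostat_decay_tau = homeostat_decay_tau,
      artifact_probability = artifact_probability,
      sd_window = sd_window,
      sd_efficiency = sd_efficiency,
      wheel_rate_light = wheel_rate_light,
      wheel_rate_dark = wheel_rate_dark,
      expression_n_genes = expression_n_genes,
      expression_n_planted = expression_n_planted,
      expression_effect_log2fc = expression_effect_log2fc,
      expression_attenuation = expression_attenuation,
      expression_noise_sd = expression_noise_sd,
      expression_n_replicates = expression_n_replicates,
      schedule = schedule
    ),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

#' Default vigilance-state transition matrix
#'
#' Per-epoch (4 s) transition probabilities over WAKE/NREM/REM. The stationary
#' distribution is roughly 55% wake, 36% NREM and 9% REM over 24 h, with bout
#' durations of a few minutes — plausible for an adult mouse. `WAKE -> REM` is
#' 0 (direct wake-to-REM transitions are not physiological in mice).
#'
#' @return A 3x3 row-stochastic matrix with dimnames WAKE/NREM/REM.
#' @export
default_transition_matrix <- function() {
  m <- matrix(
    c(
      0.970, 0.030, 0.000,
      0.025, 0.950, 0.025,
      0.080, 0.020, 0.900
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(VIGILANCE_STATES, VIGILANCE_STATES)
  )
  m
}

validate_sim_config <- function(cfg) {
  P <- cfg$base_transition_matrix
  if (!is.matrix(P) || any(dim(P) != c(3, 3))) {
    abort("`base_transition_matrix` must be a 3x3 matrix over WAKE/NREM/REM.")
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    abort("Each row of `base_transition_matrix` must be non-negative and sum to 1.")
  }
  if (P["WAKE", "REM"] != 0) {
    abort("Direct WAKE -> REM transitions are forbidden; set that entry to 0.")
  }
  num_nonneg <- c(
    "epoch_seconds", "sampling_rate", "recording_days",
    "diurnal_modulation_depth", "theta_bandwidth", "theta_gain", "delta_gain",
    "wake_gain", "homeostat_rise_tau", "homeostat_decay_tau",
    "wheel_rate_light", "wheel_rate_dark", "expression_noise_sd"
  )
  for (nm in num_nonneg) {
    if (any(cfg[[nm]] < 0)) abort(paste0("`", nm, "` must be non-negative."))
  }
  if (cfg$sd_efficiency < 0 || cfg$sd_efficiency > 1) {
    abort("`sd_efficiency` must lie in [0, 1].")
  }
  if (cfg$artifact_probability < 0 || cfg$artifact_probability > 1) {
    abort("`artifact_probability` must lie in [0, 1].")
  }
  if (length(cfg$sd_window) != 2 || diff(cfg$sd_window) <= 0) {
    abort("`sd_window` must be an increasing ZT interval c(start, end).")
  }
  if (cfg$expression_n_planted > cfg$expression_n_genes) {
    abort("`expression_n_planted` cannot exceed `expression_n_genes`.")
  }
  if (cfg$expression_n_replicates < 2) {
    abort("At least 2 replicates per cell are required (the screen needs a variance estimate).")
  }
  # The modulated probabilities must stay in [0, 1] for every epoch; check the
  # worst case m = 1 + A here so misconfiguration fails fast.
  A <- max(cfg$diurnal_modulation_depth)
  sleepy <- P
  diag(sleepy) <- 0
  if (any(sleepy[, c("NREM", "REM")] * (1 + A) > 1)) {
    abort("Modulated sleep-entry probability exceeds 1; reduce `diurnal_modulation_depth`.")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<sim_config> %d animals/group, %d day(s), %g-s epochs @ %g Hz\n",
      "  modulation depth: %s (phase ZT%g)\n",
      "  theta centers (Hz): %s; homeostat: %s\n"
    ),
    x$n_animals_per_group, x$recording_days, x$epoch_seconds, x$sampling_rate,
    paste(names(x$diurnal_modulation_depth), x$diurnal_modulation_depth,
      sep = "=", collapse = ", "
    ),
    x$modulation_phase,
    paste(names(x$theta_center_frequency), x$theta_center_frequency,
      sep = "=", collapse = ", "
    ),
    if (isTRUE(x$homeostat_enabled)) "enabled" else "disabled"
  ))
  invisible(x)
}

# Resolve a per-group parameter (named vector or scalar) for a group label.
group_param <- function(values, group, what) {
  if (length(values) == 1 && is.null(names(values))) {
    return(unname(values))
  }
  if (!group %in% names(values)) {
    abort(paste0("No `", what, "` entry for group '", group, "'."))
  }
  unname(values[[group]])
}
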