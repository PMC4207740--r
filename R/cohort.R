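#' Simulate a two-group cohort
#'
#' Generates per-animal hypnograms (optionally with the sleep-deprivation
#' protocol applied on day 2), wheel-activity series and one shared expression
#' matrix. Each animal draws from its own pseudo-random substream derived
#' from (master seed, animal index), so enlarging the cohort never changes
#' previously generated animals.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed.
#' @param groups Group labels; each must index the per-group config
#'   parameters.
#' @param sleep_deprivation Apply enforced wakefulness in `config$sd_window`
#'   on day 2 (requires `recording_days >= 2`).
#' @param wheel_days Days of wheel recording per animal (0 disables).
#' @param expression Also simulate the expression matrix.
#' @return A list of class `cohort`: `animals` (tibble: `animal_id`, `group`,
#'   `seed`), `hypnograms` (named list), `wheel` (named list of
#'   [activity_series()]), `expression` (or `NULL`), `config`, `seed`.
#' @examples
#' co <- simulate_cohort(sim_config(n_animals_per_group = 2, recording_days = 1),
#'   seed = 1,
#'   sleep_deprivation = FALSE, wheel_days = 1, expression = FALSE
#' )
#' co$animals
#' @export
simulate_cohort <- function(config, seed = 1, groups = c("WT", "MUT"),
                            sleep_deprivation = config$recording_days >= 2,
                            wheel_days = 5, expression = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  animals <- tidyr::expand_grid(group = groups, idx = seq_len(config$n_animals_per_group))
  animals$animal_id <- paste0(animals$group, "_", sprintf("%02d", animals$idx))
  # substreams keyed by (group, index) so cohort growth never perturbs
  # existing animals
  animals$seed <- substream_seed(
    seed, match(animals$group, groups) * 1000L + animals$idx
  )

  hyps <- purrr::pmap(animals, function(group, idx, animal_id, seed) {
    hyp <- simulate_hypnogram(config, group, seed = seed)
    if (sleep_deprivation) {
      if (config$recording_days < 2) {
        abort("Sleep deprivation needs at least 2 recording days (day 2 is the SD day).")
      }
      hyp <- apply_sleep_deprivation(
        hyp, 24 + config$sd_window, config$sd_efficiency,
        seed = substream_seed(seed, 1)
      )
    }
    hyp
  })
  names(hyps) <- animals$animal_id

  wheel <- NULL
  if (wheel_days > 0) {
    wheel <- purrr::pmap(animals, function(group, idx, animal_id, seed) {
      simulate_wheel_activity(config, group,
        seed = substream_seed(seed, 2),
        n_days = wheel_days
      )
    })
    names(wheel) <- animals$animal_id
  }

  em <- if (expression) {
    simulate_expression(config, seed = substream_seed(seed, 999), genotypes = groups)
  }

  structure(
    list(
      animals = animals[, c("animal_id", "group", "seed")],
      hypnograms = hyps, wheel = wheel, expression = em,
      config = config, seed = seed
    ),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "<cohort> %d animals (%s); wheel: %s; expression: %s\n",
    nrow(x$animals), paste(unique(x$animals$group), collapse = ", "),
    if (is.null(x$wheel)) "no" else "yes",
    if (is.null(x$expression)) "no" else "yes"
  ))
  invisible(x)
}

#' Per-animal light-dark amplitudes for a cohort
#'
#' Convenience wrapper: [state_fractions()] then [ld_amplitude()] for every
#' animal, stacked into one tidy table.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param bin_hours Bin width passed to [state_fractions()].
#' @param day Restrict to one recording day (1-based); `NULL` uses the whole
#'   recording. The baseline day is the usual choice when day 2 carries the
#'   SD protocol.
#' @param normalized Passed to [ld_amplitude()].
#' @return Tidy tibble: `animal_id`, `group`, `state`, `amplitude`.
#' @export
cohort_ld_amplitudes <- function(cohort, bin_hours = 2, day = 1,
                                 normalized = FALSE) {
  purrr::map2_dfr(
    cohort$hypnograms, cohort$animals$animal_id,
    function(hyp, id) {
      if (!is.null(day)) {
        cyc <- hyp_schedule(hyp)$cycle_hours
        sel <- hyp$zt >= (day - 1) * cyc & hyp$zt < day * cyc
        hyp <- hypnogram(hyp$state[sel],
          artifact = hyp$artifact[sel],
          epoch_seconds = epoch_seconds(hyp),
          start_zt = 0, schedule = hyp_schedule(hyp)
        )
      }
      grp <- cohort$animals$group[cohort$animals$animal_id == id]
      ld_amplitude(
        state_fractions(hyp, bin_hours, animal_id = id, group = grp),
        normalized = normalized
      )
    }
  )
}
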