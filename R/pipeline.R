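#' Default pipeline configuration
#'
#' A small end-to-end demonstration configuration: a two-group cohort with
#' deep (WT-like) versus attenuated (mutant-like) diurnal sleep modulation,
#' wheel running, a planted day/night expression design, and the bundled
#' synthetic interaction graph and term collection. All entries can be
#' overridden from a YAML file with the same structure.
#'
#' @param seed Master seed.
#' @return Nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    groups = c("WT", "MUT"),
    sim = list(
      n_animals_per_group = 4, recording_days = 1
    ),
    sleep_deprivation = FALSE,
    wheel_days = 2,
    bin_hours = 2,
    wheel_bin_minutes = 18,
    spectral = list(
      tpf_interval = c(0, 12), reference_epochs = 900, min_nrem_epochs = 10
    ),
    network = list(
      graph = system.file("extdata", "synthetic_interactions.tsv",
        package = "chronosleep"
      ),
      terms = system.file("extdata", "synthetic_terms.gmt",
        package = "chronosleep"
      ),
      extra_seeds = c("BHLHE41", "BHLHE40")
    )
  )
}

PIPELINE_STAGES <- c(
  "simulate", "architecture", "spectral", "screen", "network", "stats"
)

load_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort(paste0("Config file not found: ", config),
        class = "chronosleep_config_error"
      )
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort("Config must be a list or a YAML file path.",
      class = "chronosleep_config_error"
    )
  }
  base <- default_pipeline_config()
  cfg <- modifyList(base, config)
  cfg$sim_config <- tryCatch(
    do.call(sim_config, cfg$sim %||% list()),
    error = function(e) {
      abort(paste0("Invalid simulation settings: ", conditionMessage(e)),
        class = "chronosleep_config_error"
      )
    }
  )
  cfg
}

require_input <- function(path, stage) {
  if (!file.exists(path)) {
    abort(
      paste0("Stage '", stage, "' needs missing input: ", path),
      class = "chronosleep_missing_input"
    )
  }
  path
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: `simulate` writes a
#' synthetic cohort (hypnogram TSVs, wheel CSVs, expression CSVs plus ground
#' truth); `architecture` scores time budgets, L-D amplitudes and activity
#' profiles from the on-disk hypnograms and wheel files; `spectral`
#' re-synthesizes the EEG deterministically from the stored per-animal seeds
#' and computes normalized SWA time courses and theta peak frequencies;
#' `screen` runs the day/night expression screen per genotype plus the
#' attenuation comparison; `network` builds the seed-gene shortest-path model
#' from the WT pass list and scores term enrichment; `stats` compares the
#' groups (two-way ANOVA on amplitudes, Mann-Whitney per state). Every stage
#' reads only on-disk intermediates, so any stage can be re-run in isolation.
#'
#' @param config A nested list (see [default_pipeline_config()]) or path to a
#'   YAML file with the same structure.
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stage names.
#' @param quiet Suppress progress messages.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir,
                         stages = c("simulate", "architecture", "screen", "stats"),
                         quiet = FALSE) {
  cfg <- load_pipeline_config(config)
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown) > 0) {
    abort(paste0("Unknown stage(s): ", paste(unknown, collapse = ", ")),
      class = "chronosleep_unknown_stage"
    )
  }
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  timings <- list()
  for (st in stages) {
    t0 <- Sys.time()
    say("[%s] starting", st)
    switch(st,
      simulate = stage_simulate(cfg, out_dir),
      architecture = stage_architecture(cfg, out_dir),
      spectral = stage_spectral(cfg, out_dir),
      screen = stage_screen(cfg, out_dir),
      network = stage_network(cfg, out_dir),
      stats = stage_stats(cfg, out_dir)
    )
    timings[[st]] <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    say("[%s] done in %.1f s", st, timings[[st]])
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  manifest <- list(
    package = "chronosleep",
    version = as.character(utils::packageVersion("chronosleep")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg[setdiff(names(cfg), "sim_config")]),
    stages = stages,
    timings_s = timings,
    files = lapply(files, function(f) {
      list(
        path = f,
        bytes = file.size(file.path(out_dir, f)),
        sha = rlang::hash_file(file.path(out_dir, f))[[1]]
      )
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}

stage_simulate <- function(cfg, out_dir) {
  co <- simulate_cohort(cfg$sim_config,
    seed = cfg$seed, groups = cfg$groups,
    sleep_deprivation = isTRUE(cfg$sleep_deprivation),
    wheel_days = cfg$wheel_days, expression = TRUE
  )
  readr::write_csv(co$animals, file.path(out_dir, "animals.csv"), progress = FALSE)
  hyp_dir <- file.path(out_dir, "hypnograms")
  dir.create(hyp_dir, showWarnings = FALSE)
  purrr::iwalk(co$hypnograms, function(hyp, id) {
    write_hypnogram_tsv(hyp, file.path(hyp_dir, paste0(id, ".tsv")))
  })
  if (!is.null(co$wheel)) {
    wheel_dir <- file.path(out_dir, "wheel")
    dir.create(wheel_dir, showWarnings = FALSE)
    purrr::iwalk(co$wheel, function(s, id) {
      write_activity_csv(s, file.path(wheel_dir, paste0(id, ".csv")))
    })
  }
  if (!is.null(co$expression)) {
    write_expression_csv(co$expression, file.path(out_dir, "expression"))
  }
  invisible(NULL)
}

read_animals <- function(out_dir, stage) {
  readr::read_csv(require_input(file.path(out_dir, "animals.csv"), stage),
    show_col_types = FALSE, progress = FALSE
  )
}

stage_architecture <- function(cfg, out_dir) {
  animals <- read_animals(out_dir, "architecture")
  summaries <- purrr::pmap_dfr(animals, function(animal_id, group, seed) {
    hyp <- read_hypnogram_tsv(
      require_input(
        file.path(out_dir, "hypnograms", paste0(animal_id, ".tsv")),
        "architecture"
      )
    )
    tibble::as_tibble(
      state_fractions(hyp, cfg$bin_hours, animal_id = animal_id, group = group)
    )
  })
  readr::write_csv(summaries, file.path(out_dir, "vigilance_summary.csv"),
    progress = FALSE
  )
  amps <- summaries |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_modify(function(d, key) {
      ld_amplitude(structure(d, class = c("vigilance_summary", class(d))))
    }) |>
    dplyr::ungroup()
  readr::write_csv(amps, file.path(out_dir, "ld_amplitude.csv"), progress = FALSE)

  wheel_dir <- file.path(out_dir, "wheel")
  if (dir.exists(wheel_dir)) {
    profiles <- purrr::pmap_dfr(animals, function(animal_id, group, seed) {
      s <- read_activity_csv(file.path(wheel_dir, paste0(animal_id, ".csv")))
      p <- bin_activity(s, cfg$wheel_bin_minutes)
      dplyr::mutate(tibble::as_tibble(p), animal_id = animal_id, group = group)
    })
    readr::write_csv(profiles, file.path(out_dir, "activity_profile.csv"),
      progress = FALSE
    )
  }
  invisible(NULL)
}

stage_spectral <- function(cfg, out_dir) {
  animals <- read_animals(out_dir, "spectral")
  rows <- purrr::pmap_dfr(animals, function(animal_id, group, seed) {
    hyp <- read_hypnogram_tsv(
      require_input(
        file.path(out_dir, "hypnograms", paste0(animal_id, ".tsv")),
        "spectral"
      )
    )
    rec <- synthesize_signals(hyp, cfg$sim_config, group, seed = seed + 1L)
    ref <- swa_reference(rec, hyp, n_epochs = cfg$spectral$reference_epochs)
    tc <- swa_timecourse(rec, hyp, ref,
      bin_hours = cfg$bin_hours,
      min_epochs = cfg$spectral$min_nrem_epochs
    )
    tc$animal_id <- animal_id
    tc$group <- group
    sp <- mean_state_spectrum(rec, hyp, "REM", cfg$spectral$tpf_interval)
    tpf <- theta_peak_frequency(sp)
    tc$tpf <- tpf$tpf[1]
    tc
  })
  readr::write_csv(
    dplyr::select(rows, "animal_id", "group", dplyr::everything()),
    file.path(out_dir, "swa_timecourse.csv"),
    progress = FALSE
  )
  tpf_tbl <- dplyr::distinct(rows, .data$animal_id, .data$group, .data$tpf)
  readr::write_csv(tpf_tbl, file.path(out_dir, "tpf.csv"), progress = FALSE)
  invisible(NULL)
}

stage_screen <- function(cfg, out_dir) {
  require_input(file.path(out_dir, "expression_matrix.csv"), "screen")
  em <- read_expression_csv(file.path(out_dir, "expression"))
  res <- lapply(cfg$groups, function(g) day_night_screen(em, g))
  names(res) <- cfg$groups
  for (g in cfg$groups) {
    readr::write_csv(tibble::as_tibble(res[[g]]),
      file.path(out_dir, paste0("screen_", tolower(g), ".csv")),
      progress = FALSE
    )
  }
  att <- amplitude_attenuation(res[[1]], res[[2]])
  readr::write_csv(att$table, file.path(out_dir, "attenuation.csv"),
    progress = FALSE
  )
  invisible(NULL)
}

stage_network <- function(cfg, out_dir) {
  screen_path <- require_input(
    file.path(out_dir, paste0("screen_", tolower(cfg$groups[1]), ".csv")),
    "network"
  )
  screen <- readr::read_csv(screen_path, show_col_types = FALSE, progress = FALSE)
  graph <- read_edge_list(require_input(cfg$network$graph, "network"))
  seeds <- unique(c(screen$gene_id[screen$pass], cfg$network$extra_seeds))
  model <- shortest_path_network(graph, seeds)
  readr::write_csv(tidy(model), file.path(out_dir, "network_nodes.csv"),
    progress = FALSE
  )
  readr::write_csv(model$edges, file.path(out_dir, "network_edges.csv"),
    progress = FALSE
  )
  terms <- read_gmt(require_input(cfg$network$terms, "network"))
  enr <- hypergeometric_enrichment(model$nodes$node, terms, graph$nodes)
  readr::write_csv(tidy(enr), file.path(out_dir, "enrichment.csv"),
    progress = FALSE
  )
  invisible(NULL)
}

stage_stats <- function(cfg, out_dir) {
  amps <- readr::read_csv(
    require_input(file.path(out_dir, "ld_amplitude.csv"), "stats"),
    show_col_types = FALSE, progress = FALSE
  )
  aov_tab <- two_way_anova(amps, "amplitude", "group", "state")
  readr::write_csv(tidy(aov_tab), file.path(out_dir, "stats_anova.csv"),
    progress = FALSE
  )
  groups <- unique(amps$group)
  mw <- purrr::map_dfr(unique(amps$state), function(s) {
    x <- amps$amplitude[amps$state == s & amps$group == groups[1]]
    y <- amps$amplitude[amps$state == s & amps$group == groups[2]]
    dplyr::mutate(mann_whitney_u(x, y), state = s, .before = 1)
  })
  readr::write_csv(mw, file.path(out_dir, "stats_mann_whitney.csv"),
    progress = FALSE
  )
  invisible(NULL)
}
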