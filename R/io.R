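#' Read and write hypnograms as TSV
#'
#' The on-disk format has columns `epoch_index`, `zt_start_s`, `state`,
#' `artifact` — the epoch table produced by scoring software or by the
#' cohort generator.
#'
#' @param hyp A [hypnogram()].
#' @param path File path.
#' @return `write_hypnogram_tsv()` returns `path` invisibly;
#'   `read_hypnogram_tsv()` returns a [hypnogram()].
#' @export
write_hypnogram_tsv <- function(hyp, path) {
  hyp <- as_hypnogram(hyp)
  readr::write_tsv(
    tibble::tibble(
      epoch_index = hyp$epoch,
      zt_start_s = round(hyp$zt * 3600, 3),
      state = hyp$state,
      artifact = as.integer(hyp$artifact)
    ),
    path, progress = FALSE
  )
  invisible(path)
}

#' @rdname write_hypnogram_tsv
#' @param epoch_seconds,schedule Metadata for the reconstructed hypnogram;
#'   the epoch length defaults to the spacing of `zt_start_s`.
#' @export
read_hypnogram_tsv <- function(path, epoch_seconds = NULL,
                               schedule = light_schedule()) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  eps <- epoch_seconds %||%
    (if (nrow(df) > 1) df$zt_start_s[2] - df$zt_start_s[1] else 4)
  hypnogram(df$state,
    artifact = as.logical(df$artifact), epoch_seconds = eps,
    start_zt = if (nrow(df) > 0) df$zt_start_s[1] / 3600 else 0,
    schedule = schedule
  )
}

#' Read and write wheel-count series as CSV
#'
#' Columns `minute`, `zt`, `count`.
#'
#' @param series An [activity_series()].
#' @param path File path.
#' @export
write_activity_csv <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_activity_csv
#' @param schedule A [light_schedule()].
#' @export
read_activity_csv <- function(path, schedule = light_schedule()) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  activity_series(df$count,
    start_zt = if (nrow(df) > 0) df$zt[1] else 0,
    schedule = schedule
  )
}

#' Write an expression matrix and its sample annotation
#'
#' The matrix goes to `<stem>_matrix.csv` (first column `gene_id`), the
#' annotation to `<stem>_samples.csv`, and — for simulated data — the
#' ground-truth planted set to `<stem>_truth.json`.
#'
#' @param em An `expression_matrix`.
#' @param stem Path stem (no extension).
#' @return The paths written, invisibly.
#' @export
write_expression_csv <- function(em, stem) {
  mat_path <- paste0(stem, "_matrix.csv")
  readr::write_csv(
    dplyr::bind_cols(
      tibble::tibble(gene_id = rownames(em$values)),
      tibble::as_tibble(em$values)
    ),
    mat_path,
    progress = FALSE
  )
  smp_path <- paste0(stem, "_samples.csv")
  readr::write_csv(em$samples, smp_path, progress = FALSE)
  paths <- c(mat_path, smp_path)
  if (!is.null(em$planted)) {
    truth_path <- paste0(stem, "_truth.json")
    jsonlite::write_json(
      list(
        planted = em$planted, effect_log2fc = em$effect_log2fc,
        attenuation = em$attenuation
      ),
      truth_path,
      auto_unbox = TRUE, pretty = TRUE
    )
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

#' @rdname write_expression_csv
#' @param stem Path stem used when writing.
#' @export
read_expression_csv <- function(stem) {
  mat <- readr::read_csv(paste0(stem, "_matrix.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  vals <- as.matrix(mat[, -1])
  rownames(vals) <- mat$gene_id
  samples <- readr::read_csv(paste0(stem, "_samples.csv"),
    show_col_types = FALSE, progress = FALSE
  )
  truth_path <- paste0(stem, "_truth.json")
  planted <- NULL
  effect <- NULL
  att <- NULL
  if (file.exists(truth_path)) {
    truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    planted <- truth$planted
    effect <- truth$effect_log2fc
    att <- truth$attenuation
  }
  structure(
    list(
      values = vals, samples = samples, planted = planted,
      effect_log2fc = effect, attenuation = att
    ),
    class = "expression_matrix"
  )
}

#' Write recording channels as CSV
#'
#' One column per channel at full sampling rate; intended for short excerpts
#' and interoperability, not for long recordings.
#'
#' @param recording An [epoched_recording()].
#' @param path File path.
#' @export
write_recording_csv <- function(recording, path) {
  readr::write_csv(tibble::as_tibble(recording$channels), path, progress = FALSE)
  invisible(path)
}
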