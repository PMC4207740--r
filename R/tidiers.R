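#' Tidy an ANOVA table
#'
#' @param x A [two_way_anova()] result.
#' @param ... Unused.
#' @return Tibble with `term`, `sumsq`, `df`, `statistic`, `p.value`.
#' @export
tidy.sleep_anova <- function(x, ...) {
  tibble::tibble(
    term = x$term, sumsq = x$sumsq, df = x$df,
    statistic = x$statistic, p.value = x$p_value
  )
}

#' @rdname tidy.sleep_anova
#' @export
glance.sleep_anova <- function(x, ...) {
  fit <- attr(x, "fit")
  s <- summary(fit)
  tibble::tibble(
    r.squared = s$r.squared,
    df.residual = fit$df.residual,
    nobs = length(fit$residuals),
    ss_type = attr(x, "type"),
    note = attr(x, "note")
  )
}

#' Tidy a day/night screen
#'
#' @param x A [day_night_screen()] result.
#' @param ... Unused.
#' @export
tidy.screen_result <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname tidy.screen_result
#' @export
glance.screen_result <- function(x, ...) {
  tibble::tibble(
    genotype = attr(x, "genotype"),
    n_genes = nrow(x),
    n_pass = sum(x$pass),
    n_up = sum(x$pass & x$log2_fc > 0),
    n_down = sum(x$pass & x$log2_fc < 0),
    fc_cutoff = attr(x, "fc_cutoff"),
    p_cutoff = attr(x, "p_cutoff"),
    method = attr(x, "method")
  )
}

#' Tidy an enrichment result
#'
#' @param x A [hypergeometric_enrichment()] result.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$overlap <- vapply(out$overlap, paste, character(1), collapse = ";")
  out
}

#' Tidy a network model into its node table
#'
#' @param x A [shortest_path_network()] result.
#' @param ... Unused.
#' @export
tidy.network_model <- function(x, ...) {
  deg <- table(c(x$edges$from, x$edges$to))
  out <- x$nodes
  out$degree <- as.integer(deg[out$node])
  out$degree[is.na(out$degree)] <- 0L
  out
}

#' @rdname tidy.network_model
#' @export
glance.network_model <- function(x, ...) {
  tibble::tibble(
    n_seeds = sum(x$nodes$role == "seed"),
    n_connectors = sum(x$nodes$role == "connector"),
    n_edges = nrow(x$edges),
    n_missing_seeds = length(x$missing_seeds)
  )
}
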