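# Gene symbols used for the planted day/night-regulated transcripts so that
# the screen output interlocks with the bundled synthetic interaction graph;
# activity-induced IEGs, neuropeptides, receptors, myelin and clock genes.
PLANTED_SYMBOLS <- c(
  "FOS", "EGR1", "JUNB", "NR4A1", "IER1", "PENK", "TAC1", "DUSP1", "DUSP6",
  "DRD2", "ADORA2A", "ENPP2", "PLP1", "CLDN11", "PER1", "PER2", "CRY1",
  "HSPA1B", "ANLN", "TTR", "DBP", "NR1D1"
)

#' Synthetic day/night expression matrix
#'
#' Simulates a log2 expression matrix (genes x samples) for two genotypes
#' sampled at ZT4 (wake phase) and ZT16 (sleep phase). Planted genes carry a
#' `+expression_effect_log2fc` shift at ZT16 in the WT-like group and an
#' attenuated effect (`expression_attenuation` times the WT effect) in the
#' mutant-like group; all values carry Gaussian noise. The first planted
#' genes are named after canonical activity-induced and clock transcripts so
#' downstream network analysis has meaningful identifiers; the ground-truth
#' planted set is returned alongside.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param genotypes Labels of the WT-like and mutant-like group, in that order.
#' @return A list of class `expression_matrix`: `values` (numeric matrix,
#'   genes x samples, log2 scale), `samples` (tibble: `sample_id`, `genotype`,
#'   `timepoint`, `replicate`), `planted` (character vector of planted gene
#'   ids), `effect_log2fc`, `attenuation`.
#' @examples
#' em <- simulate_expression(sim_config(expression_n_genes = 50), seed = 1)
#' head(em$planted)
#' @export
simulate_expression <- function(config, seed = 1, genotypes = c("WT", "MUT")) {
  stopifnot(inherits(config, "sim_config"))
  ng <- config$expression_n_genes
  np <- config$expression_n_planted
  nrep <- config$expression_n_replicates
  if (nrep < 2) abort("At least 2 replicates per cell are required.")

  gene_ids <- sprintf("GENE%04d", seq_len(ng))
  if (np > 0) {
    sym <- head(PLANTED_SYMBOLS, np)
    if (np > length(PLANTED_SYMBOLS)) {
      sym <- c(sym, sprintf("PLANTED%03d", seq_len(np - length(PLANTED_SYMBOLS))))
    }
    gene_ids[seq_len(np)] <- sym
  }
  samples <- tidyr::expand_grid(
    genotype = genotypes,
    timepoint = c("ZT4", "ZT16"),
    replicate = seq_len(nrep)
  )
  samples$sample_id <- paste(samples$genotype, samples$timepoint,
    samples$replicate,
    sep = "_"
  )

  effect <- config$expression_effect_log2fc
  att <- config$expression_attenuation
  baseline <- 8 # arbitrary log2 abundance level
  with_rng(seed, {
    base_level <- rnorm(ng, baseline, 1) # gene-specific abundance
    vals <- matrix(rnorm(ng * nrow(samples), sd = config$expression_noise_sd),
      nrow = ng
    )
    vals <- vals + base_level
    night <- samples$timepoint == "ZT16"
    wt <- samples$genotype == genotypes[1]
    if (np > 0) {
      shift <- outer(
        c(rep(1, np), rep(0, ng - np)),
        night * ifelse(wt, effect, effect * att)
      )
      vals <- vals + shift
    }
    dimnames(vals) <- list(gene_ids, samples$sample_id)
    structure(
      list(
        values = vals,
        samples = samples[, c("sample_id", "genotype", "timepoint", "replicate")],
        planted = gene_ids[seq_len(np)],
        effect_log2fc = effect,
        attenuation = att
      ),
      class = "expression_matrix"
    )
  })
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "<expression_matrix> %d genes x %d samples (%d planted day/night genes)\n",
    nrow(x$values), ncol(x$values), length(x$planted)
  ))
  invisible(x)
}

#' Day/night differential-expression screen
#'
#' Per-gene comparison of ZT16 versus ZT4 samples of one genotype on the log2
#' scale, with Benjamini-Hochberg adjustment across genes. A gene passes when
#' its linear fold-change magnitude strictly exceeds `fc_cutoff` AND its
#' adjusted p-value is below `p_cutoff`. The direction sign is retained (a
#' negative log2 fold-change flags down-regulation at ZT16).
#'
#' `method = "moderated"` (default) shrinks each gene's pooled variance
#' toward a common prior (fixed prior df), the variance-moderation approach
#' standard for small replicate numbers on arrays; `method = "welch"` uses a
#' plain per-gene Welch two-sample t-test instead.
#'
#' @param em An [simulate_expression()] result, or any list with `values`
#'   (log2 matrix) and `samples` (tibble with `sample_id`, `genotype`,
#'   `timepoint`).
#' @param genotype Genotype to screen.
#' @param fc_cutoff Linear fold-change cut-off (strict inequality).
#' @param p_cutoff Adjusted p-value cut-off.
#' @param method `"moderated"` or `"welch"`.
#' @param prior_df Prior degrees of freedom for `method = "moderated"`.
#' @return A tibble of class `screen_result`: `gene_id`, `log2_fc`,
#'   `fold_change` (signed linear scale: negative values mark ZT16
#'   down-regulation, magnitude `2^|log2_fc|`), `p_value`, `adj_p_value`,
#'   `pass`.
#' @examples
#' em <- simulate_expression(sim_config(expression_n_genes = 100), seed = 1)
#' res <- day_night_screen(em, "WT")
#' sum(res$pass)
#' @export
day_night_screen <- function(em, genotype, fc_cutoff = 1.5, p_cutoff = 0.05,
                             method = c("moderated", "welch"), prior_df = 4) {
  method <- match.arg(method)
  vals <- em$values
  samples <- em$samples
  if (is.null(vals) || is.null(samples)) {
    abort("`em` must carry `values` and `samples`.")
  }
  if (!all(c("genotype", "timepoint") %in% names(samples))) {
    abort("Sample annotation must contain `genotype` and `timepoint`.")
  }
  sel <- samples$genotype == genotype
  if (!any(sel)) abort(paste0("No samples for genotype '", genotype, "'."))
  night <- sel & samples$timepoint %in% c("ZT16", "CT16")
  day <- sel & samples$timepoint %in% c("ZT4", "CT4")
  n1 <- sum(night)
  n2 <- sum(day)
  if (n1 < 2 || n2 < 2) {
    abort("At least 2 replicates per timepoint are required.")
  }
  xn <- vals[, night, drop = FALSE]
  xd <- vals[, day, drop = FALSE]
  m1 <- unname(rowMeans(xn))
  m2 <- unname(rowMeans(xd))
  v1 <- unname(apply(xn, 1, var))
  v2 <- unname(apply(xd, 1, var))
  d <- m1 - m2

  if (method == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    tstat <- d / sqrt(se2)
    p <- 2 * pt(-abs(tstat), df)
    # degenerate genes: zero variance in both groups
    flat <- se2 == 0
    p[flat & d == 0] <- 1
    p[flat & d != 0] <- 0
  } else {
    dfp <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / dfp
    s0 <- mean(s2)
    s2_shrunk <- (prior_df * s0 + dfp * s2) / (prior_df + dfp)
    tstat <- d / sqrt(s2_shrunk * (1 / n1 + 1 / n2))
    p <- 2 * pt(-abs(tstat), dfp + prior_df)
    flat <- s2_shrunk == 0
    p[flat & d == 0] <- 1
    p[flat & d != 0] <- 0
  }
  adj <- p.adjust(p, method = "BH")
  fc_lin <- sign(d) * 2^abs(d)
  fc_lin[d == 0] <- 1
  out <- tibble::tibble(
    gene_id = rownames(vals),
    log2_fc = d,
    fold_change = fc_lin,
    p_value = p,
    adj_p_value = adj,
    pass = (2^abs(d) > fc_cutoff) & (adj < p_cutoff)
  )
  structure(out,
    genotype = genotype, fc_cutoff = fc_cutoff, p_cutoff = p_cutoff,
    method = method,
    class = c("screen_result", class(tibble::tibble()))
  )
}

#' Genotype attenuation of day/night fold-changes
#'
#' Compares two screens over the same gene universe: per gene, the ratio of
#' the mutant to the WT fold-change is reported on the log2 scale
#' (`ratio_log2 = log2_fc_mut / log2_fc_wt`) and on the linear scale
#' (`ratio_linear = 2^(log2_fc_mut - log2_fc_wt)`), together with the
#' partition of the pass lists into WT-only, shared and mutant-only genes.
#'
#' @param result_wt,result_mut Two [day_night_screen()] results over the same
#'   genes.
#' @return A list of class `attenuation_result`: `table` (per-gene tibble),
#'   `wt_only`, `shared`, `mut_only` (character vectors of gene ids).
#' @export
amplitude_attenuation <- function(result_wt, result_mut) {
  if (!setequal(result_wt$gene_id, result_mut$gene_id)) {
    abort("The two screens cover different gene sets.")
  }
  mut <- result_mut[match(result_wt$gene_id, result_mut$gene_id), ]
  tab <- tibble::tibble(
    gene_id = result_wt$gene_id,
    log2_fc_wt = result_wt$log2_fc,
    log2_fc_mut = mut$log2_fc,
    ratio_log2 = mut$log2_fc / result_wt$log2_fc,
    ratio_linear = 2^(mut$log2_fc - result_wt$log2_fc),
    pass_wt = result_wt$pass,
    pass_mut = mut$pass
  )
  structure(
    list(
      table = tab,
      wt_only = tab$gene_id[tab$pass_wt & !tab$pass_mut],
      shared = tab$gene_id[tab$pass_wt & tab$pass_mut],
      mut_only = tab$gene_id[!tab$pass_wt & tab$pass_mut]
    ),
    class = "attenuation_result"
  )
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat(sprintf(
    "<attenuation_result> pass lists: %d WT-only, %d shared, %d mutant-only\n",
    length(x$wt_only), length(x$shared), length(x$mut_only)
  ))
  invisible(x)
}
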