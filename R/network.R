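#' Molecular interaction graph from an edge table
#'
#' Identifiers are case-normalized (upper-cased), self-loops dropped and — in
#' undirected mode — duplicate edges collapsed regardless of orientation. An
#' optional synonym map (protein name -> gene symbol) is applied before
#' normalization.
#'
#' @param edges Data frame with columns `from`, `to` (extra columns such as an
#'   interaction type are preserved).
#' @param directed Interpret edges as directed.
#' @param synonyms Optional named character vector mapping alternative
#'   identifiers to canonical ones.
#' @return A list of class `interaction_graph`: `edges` (tibble), `nodes`
#'   (character), `directed`.
#' @export
interaction_graph <- function(edges, directed = FALSE, synonyms = NULL) {
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have `from` and `to` columns.")
  }
  canon <- function(x) {
    x <- toupper(as.character(x))
    if (!is.null(synonyms)) {
      syn <- setNames(toupper(as.character(synonyms)), toupper(names(synonyms)))
      hit <- x %in% names(syn)
      x[hit] <- unname(syn[x[hit]])
    }
    x
  }
  ed <- tibble::as_tibble(edges)
  ed$from <- canon(ed$from)
  ed$to <- canon(ed$to)
  ed <- ed[ed$from != ed$to, , drop = FALSE]
  key <- if (directed) {
    paste(ed$from, ed$to, sep = "\r")
  } else {
    paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "\r")
  }
  ed <- ed[!duplicated(key), , drop = FALSE]
  structure(
    list(
      edges = ed,
      nodes = sort(unique(c(ed$from, ed$to))),
      directed = directed
    ),
    class = "interaction_graph"
  )
}

#' Read a TSV edge list
#'
#' Expects columns `from` and `to` (header required); extra columns are kept.
#'
#' @param path File path.
#' @inheritParams interaction_graph
#' @return An [interaction_graph()].
#' @export
read_edge_list <- function(path, directed = FALSE, synonyms = NULL) {
  interaction_graph(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    directed = directed, synonyms = synonyms
  )
}

#' Shortest-path subnetwork around seed genes
#'
#' Builds the most stringent shortest-path model: the network contains every
#' seed present in the graph, all direct seed-seed edges and, with
#' `max_intermediates = 1`, every non-seed node that lies on a
#' seed-connector-seed path (i.e. is adjacent to at least two distinct seeds)
#' together with the edges of those paths. Only edges on admitted seed-pair
#' paths are kept — connector-connector edges are not. In directed mode a
#' connector must have an in-edge from one seed and an out-edge to a
#' *different* seed.
#'
#' @param graph An [interaction_graph()].
#' @param seeds Character vector of seed identifiers (case-insensitive).
#'   Seeds absent from the graph are reported via a message, not an error.
#' @param max_intermediates 0 (direct edges only) or 1 (one connector).
#' @return A list of class `network_model`: `nodes` (tibble `node`, `role`),
#'   `edges` (tibble `from`, `to`), `missing_seeds`.
#' @examples
#' g <- interaction_graph(data.frame(from = c("a", "x"), to = c("x", "b")))
#' shortest_path_network(g, c("A", "B"))
#' @export
shortest_path_network <- function(graph, seeds, max_intermediates = 1) {
  stopifnot(inherits(graph, "interaction_graph"))
  if (length(seeds) == 0) abort("Seed set is empty.")
  if (!max_intermediates %in% c(0, 1)) {
    abort("Only `max_intermediates` 0 or 1 is supported (most stringent setting).")
  }
  seeds <- unique(toupper(seeds))
  missing <- setdiff(seeds, graph$nodes)
  if (length(missing) > 0) {
    inform(paste0(
      "Seed(s) absent from the graph: ", paste(sort(missing), collapse = ", ")
    ))
  }
  seeds_in <- intersect(seeds, graph$nodes)
  ed <- graph$edges

  seed_edge <- ed$from %in% seeds_in & ed$to %in% seeds_in
  model_edges <- ed[seed_edge, c("from", "to")]

  connectors <- character(0)
  if (max_intermediates == 1 && length(seeds_in) >= 2) {
    if (graph$directed) {
      cand <- setdiff(graph$nodes, seeds_in)
      for (v in cand) {
        ins <- unique(ed$from[ed$to == v & ed$from %in% seeds_in])
        outs <- unique(ed$to[ed$from == v & ed$to %in% seeds_in])
        # a path s1 -> v -> s2 needs two distinct seeds
        if (length(ins) > 0 && length(outs) > 0 &&
          length(unique(c(ins, outs))) >= 2) {
          connectors <- c(connectors, v)
          model_edges <- dplyr::bind_rows(
            model_edges,
            tibble::tibble(from = ins, to = v),
            tibble::tibble(from = v, to = outs)
          )
        }
      }
    } else {
      touch_seed <- (ed$from %in% seeds_in) != (ed$to %in% seeds_in)
      half <- ed[touch_seed, , drop = FALSE]
      if (nrow(half) > 0) {
        other <- ifelse(half$from %in% seeds_in, half$to, half$from)
        seed_end <- ifelse(half$from %in% seeds_in, half$from, half$to)
        deg <- tapply(seed_end, other, function(s) length(unique(s)))
        connectors <- names(deg)[deg >= 2]
        keep <- other %in% connectors
        model_edges <- dplyr::bind_rows(
          model_edges,
          tibble::tibble(from = seed_end[keep], to = other[keep])
        )
      }
    }
  }
  connectors <- sort(unique(connectors))
  # canonical ordering so input order never matters
  if (!graph$directed && nrow(model_edges) > 0) {
    flip <- model_edges$from > model_edges$to
    tmp <- model_edges$from[flip]
    model_edges$from[flip] <- model_edges$to[flip]
    model_edges$to[flip] <- tmp
  }
  model_edges <- dplyr::distinct(
    dplyr::arrange(model_edges, .data$from, .data$to)
  )
  nodes <- tibble::tibble(
    node = c(sort(seeds_in), connectors),
    role = rep(c("seed", "connector"), c(length(seeds_in), length(connectors)))
  )
  structure(
    list(nodes = nodes, edges = model_edges, missing_seeds = sort(missing)),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf(
    "<network_model> %d seeds + %d connectors, %d edges\n",
    sum(x$nodes$role == "seed"), sum(x$nodes$role == "connector"),
    nrow(x$edges)
  ))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' Tab-delimited: term name, description, then member genes. Identifiers are
#' upper-cased.
#'
#' @param path File path.
#' @return A named list of character vectors (a term collection).
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(toupper(p[-(1:2)])))
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}

#' Hypergeometric term enrichment
#'
#' Per term, the upper-tail probability of observing at least the seen
#' overlap between the query and the term set under hypergeometric sampling
#' from the universe, with Benjamini-Hochberg adjustment across terms. Term
#' genes outside the universe are dropped; query genes outside the universe
#' are dropped with a logged count.
#'
#' @param query Character vector of genes of interest.
#' @param terms Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector defining the sampling frame (e.g. all
#'   graph nodes or all assayed genes).
#' @return A tibble of class `enrichment_result`: `term`, `n_term`,
#'   `n_overlap`, `p_value`, `adj_p_value`, `overlap` (list column), sorted
#'   by p-value.
#' @export
hypergeometric_enrichment <- function(query, terms, universe) {
  universe <- unique(toupper(universe))
  if (length(universe) == 0) abort("Universe is empty.")
  query <- unique(toupper(query))
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    inform(paste0(length(dropped), " query gene(s) outside the universe dropped."))
  }
  query <- intersect(query, universe)
  if (length(query) == 0) abort("Query is empty after universe filtering.")
  N <- length(universe)
  n <- length(query)
  rows <- purrr::imap_dfr(terms, function(genes, nm) {
    gs <- intersect(unique(toupper(genes)), universe)
    ov <- intersect(query, gs)
    k <- length(ov)
    K <- length(gs)
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(
      term = nm, n_term = K, n_overlap = k, p_value = p,
      overlap = list(sort(ov))
    )
  })
  rows$adj_p_value <- p.adjust(rows$p_value, method = "BH")
  rows <- rows[order(rows$p_value, rows$term), c(
    "term", "n_term", "n_overlap",
    "p_value", "adj_p_value", "overlap"
  )]
  structure(rows,
    n_universe = N, n_query = n,
    class = c("enrichment_result", class(tibble::tibble()))
  )
}
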