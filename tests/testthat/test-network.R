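test_that("single-connector and direct-edge cases build the expected model", {
  g <- interaction_graph(data.frame(from = c("A", "X"), to = c("X", "B")))
  m <- shortest_path_network(g, c("A", "B"))
  expect_setequal(m$nodes$node[m$nodes$role == "connector"], "X")
  expect_equal(nrow(m$edges), 2)

  g2 <- interaction_graph(data.frame(from = "A", to = "B"))
  m2 <- shortest_path_network(g2, c("A", "B"))
  expect_length(m2$nodes$node[m2$nodes$role == "connector"], 0)
  expect_equal(m2$edges, tibble::tibble(from = "A", to = "B"))

  # nodes touching only one seed are not admitted (seeds 3 hops apart)
  g3 <- interaction_graph(data.frame(
    from = c("A", "Y", "W"),
    to = c("Y", "W", "Z")
  ))
  m3 <- shortest_path_network(g3, c("A", "Z"))
  expect_length(m3$nodes$node[m3$nodes$role == "connector"], 0)
  expect_equal(nrow(m3$edges), 0)
})

test_that("identifier handling is case-insensitive with synonyms and no self-loops", {
  ed <- data.frame(
    from = c("fos", "FOS", "Jun", "Jun"),
    to = c("jun", "JUN", "jun", "EGR1")
  )
  g <- interaction_graph(ed)
  expect_equal(nrow(g$edges), 2) # dedup + self-loop removal
  expect_true(all(g$nodes == toupper(g$nodes)))

  gs <- interaction_graph(
    data.frame(from = "c-Fos", to = "JUN"),
    synonyms = c("C-FOS" = "FOS")
  )
  expect_setequal(gs$nodes, c("FOS", "JUN"))

  m <- suppressMessages(shortest_path_network(g, c("fos", "egr1", "ABSENT")))
  expect_equal(m$missing_seeds, "ABSENT")
  expect_true("JUN" %in% m$nodes$node[m$nodes$role == "connector"])
})

test_that("empty seeds and deeper searches are rejected", {
  g <- interaction_graph(data.frame(from = "A", to = "B"))
  expect_error(shortest_path_network(g, character(0)), "empty")
  expect_error(shortest_path_network(g, "A", max_intermediates = 2), "stringent")
})

test_that("random graphs match exhaustive <=2-hop path enumeration", {
  set.seed(99)
  for (i in seq_len(60)) {
    n <- sample(4:12, 1)
    nodes <- LETTERS[seq_len(n)]
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.3
    if (!any(keep)) next
    edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
    seeds <- sample(nodes, sample(2:4, 1))
    g <- interaction_graph(edges)
    m <- suppressMessages(shortest_path_network(g, seeds))
    orc <- oracle_path_model(edges, seeds)
    expect_setequal(m$nodes$node[m$nodes$role == "connector"], orc$connectors)
    got_edges <- paste(m$edges$from, m$edges$to, sep = "|")
    expect_setequal(got_edges, orc$edges)
  }
})

test_that("node and edge input order never changes the model", {
  edges <- data.frame(
    from = c("A", "X", "B", "C", "X"),
    to = c("X", "B", "C", "A", "C")
  )
  g1 <- interaction_graph(edges)
  g2 <- interaction_graph(edges[c(4, 2, 5, 1, 3), ])
  m1 <- shortest_path_network(g1, c("A", "B", "C"))
  m2 <- shortest_path_network(g2, c("C", "A", "B"))
  expect_equal(m1$nodes, m2$nodes)
  expect_equal(m1$edges, m2$edges)
})

test_that("adding a seed never removes connectors or edges", {
  set.seed(7)
  nodes <- LETTERS[1:10]
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < 0.35
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
  g <- interaction_graph(edges)
  seeds <- c("A", "B", "C")
  m_small <- shortest_path_network(g, seeds)
  for (extra in setdiff(nodes, seeds)) {
    m_big <- shortest_path_network(g, c(seeds, extra))
    expect_true(all(m_small$nodes$node %in% m_big$nodes$node))
    small_edges <- paste(m_small$edges$from, m_small$edges$to)
    big_edges <- paste(m_big$edges$from, m_big$edges$to)
    expect_true(all(small_edges %in% big_edges))
  }
})

test_that("directed mode demands directionally consistent seed-v-seed paths", {
  ed <- data.frame(from = c("A", "X", "B"), to = c("X", "B", "Y"))
  g <- interaction_graph(ed, directed = TRUE)
  m <- shortest_path_network(g, c("A", "B"))
  expect_setequal(m$nodes$node[m$nodes$role == "connector"], "X")
  # reversed second hop: no directed A -> v -> B path
  ed2 <- data.frame(from = c("A", "B"), to = c("X", "X"))
  g2 <- interaction_graph(ed2, directed = TRUE)
  m2 <- shortest_path_network(g2, c("A", "B"))
  expect_length(m2$nodes$node[m2$nodes$role == "connector"], 0)
})

test_that("hypergeometric p-values match exact enumeration", {
  # hand-enumerated worked case: N=10, K=4, n=5, k=4 -> 6/252
  terms <- list(T1 = paste0("g", 1:4))
  universe <- paste0("g", 1:10)
  query <- paste0("g", c(1:4, 10))
  res <- hypergeometric_enrichment(query, terms, universe)
  expect_equal(res$p_value, 6 / 252, tolerance = 1e-12)
  expect_equal(res$p_value, oracle_hyper_upper(10, 4, 5, 4), tolerance = 1e-12)

  set.seed(12)
  for (i in seq_len(25)) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    universe <- paste0("u", seq_len(N))
    term <- list(T = universe[seq_len(K)])
    query <- sample(universe, n)
    k <- sum(query %in% term$T)
    res <- hypergeometric_enrichment(query, term, universe)
    expect_equal(res$p_value, oracle_hyper_upper(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("degenerate overlaps give p = 1", {
  universe <- paste0("g", 1:20)
  res <- hypergeometric_enrichment(
    paste0("g", 1:5),
    list(DISJOINT = paste0("g", 10:15), EVERYTHING = universe),
    universe
  )
  expect_equal(res$p_value[res$term == "DISJOINT"], 1)
  expect_equal(res$p_value[res$term == "EVERYTHING"], 1)
  expect_error(hypergeometric_enrichment(character(0), list(), universe), "empty")
})

test_that("query genes outside the universe are dropped with a note", {
  expect_message(
    res <- hypergeometric_enrichment(
      c("g1", "g2", "ALIEN"),
      list(T = c("g1", "g2")), paste0("g", 1:8)
    ),
    "dropped"
  )
  expect_equal(res$n_overlap, 2)
})

test_that("BH adjustment is monotone in the ranked p-values", {
  set.seed(4)
  universe <- paste0("g", 1:30)
  terms <- lapply(1:8, function(i) sample(universe, sample(3:10, 1)))
  names(terms) <- paste0("T", 1:8)
  res <- hypergeometric_enrichment(sample(universe, 10), terms, universe)
  expect_true(all(diff(res$adj_p_value[order(res$p_value)]) >= -1e-15))
  expect_true(all(res$adj_p_value >= res$p_value - 1e-15))
})

test_that("GMT and edge-list readers parse the bundled synthetic files", {
  gmt <- read_gmt(system.file("extdata", "synthetic_terms.gmt",
    package = "chronosleep"
  ))
  expect_true("CIRCADIAN_RHYTHM" %in% names(gmt))
  expect_true("PER1" %in% gmt$CIRCADIAN_RHYTHM)
  g <- read_edge_list(system.file("extdata", "synthetic_interactions.tsv",
    package = "chronosleep"
  ))
  expect_true(all(c("CLOCK", "FOS", "BHLHE41") %in% g$nodes))
  expect_false(any(g$edges$from == g$edges$to))
})
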