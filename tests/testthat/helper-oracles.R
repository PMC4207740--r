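# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: direct DFT instead of fft-based periodograms,
# explicit path enumeration instead of the adjacency rule, pair counting
# instead of rank formulas, and closed-form sums of squares.

# Direct-DFT Welch periodogram: two non-overlapping Hann-windowed 2-s
# segments, one-sided density, averaged; 0.5-20 Hz grid.
oracle_epoch_spectrum <- function(x, fs = 256) {
  seg_len <- 2 * fs
  nseg <- length(x) %/% seg_len
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(seg_len) - 1) / seg_len))
  U <- sum(w^2)
  half <- seg_len / 2
  kmat <- outer(0:half, 0:(seg_len - 1)) # DFT matrix exponents
  E <- exp(-2i * pi * kmat / seg_len)
  acc <- 0
  for (s in seq_len(nseg)) {
    xs <- x[((s - 1) * seg_len + 1):(s * seg_len)] * w
    X <- as.vector(E %*% xs)
    P <- Mod(X)^2 / (fs * U)
    P[2:half] <- 2 * P[2:half]
    acc <- acc + P
  }
  P <- acc / nseg
  freq <- (0:half) * fs / seg_len
  keep <- freq >= 0.5 - 1e-9 & freq <= 20 + 1e-9
  list(frequency = freq[keep], power = P[keep])
}

# Mean power of a raw signal epoch in [lo, hi], via the oracle periodogram.
oracle_band_power <- function(x, lo, hi, fs = 256) {
  sp <- oracle_epoch_spectrum(x, fs)
  sel <- sp$frequency >= lo - 1e-9 & sp$frequency <= hi + 1e-9
  mean(sp$power[sel])
}

# First-order transition counts tallied by explicit looping.
oracle_transition_freqs <- function(states) {
  lv <- c("WAKE", "NREM", "REM")
  counts <- matrix(0, 3, 3, dimnames = list(lv, lv))
  for (t in seq_len(length(states) - 1)) {
    counts[states[t], states[t + 1]] <- counts[states[t], states[t + 1]] + 1
  }
  counts
}

# Brute-force shortest-path model: enumerate every simple path of length
# <= 2 between every ordered pair of distinct seeds; keep nodes and edges on
# such paths. Undirected edges given as a two-column data frame.
oracle_path_model <- function(edges, seeds) {
  seeds <- toupper(seeds)
  from <- toupper(edges$from)
  to <- toupper(edges$to)
  nodes <- unique(c(from, to))
  adj <- function(a, b) any((from == a & to == b) | (from == b & to == a))
  seeds_in <- intersect(seeds, nodes)
  keep_nodes <- seeds_in
  keep_edges <- character(0)
  ekey <- function(a, b) paste(min(a, b), max(a, b), sep = "|")
  for (s1 in seeds_in) {
    for (s2 in seeds_in) {
      if (s1 >= s2) next
      if (adj(s1, s2)) keep_edges <- c(keep_edges, ekey(s1, s2))
      for (v in setdiff(nodes, c(s1, s2))) {
        if (!(v %in% seeds_in) && adj(s1, v) && adj(v, s2)) {
          keep_nodes <- c(keep_nodes, v)
          keep_edges <- c(keep_edges, ekey(s1, v), ekey(v, s2))
        }
      }
    }
  }
  list(
    nodes = sort(unique(keep_nodes)),
    connectors = sort(setdiff(unique(keep_nodes), seeds_in)),
    edges = sort(unique(keep_edges))
  )
}

# Exact hypergeometric upper tail P(X >= k) by enumerating all draws of size
# n from a universe of size N containing K marked elements.
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Exact two-sided Mann-Whitney p by enumerating group assignments; U computed
# by direct pair counting (ties count one half).
oracle_mw <- function(x, y) {
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  vals <- c(x, y)
  nx <- length(x)
  mu <- nx * length(y) / 2
  u_obs <- u_of(x, y)
  combos <- combn(length(vals), nx)
  us <- apply(combos, 2, function(ix) u_of(vals[ix], vals[-ix]))
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9))
}

# Closed-form sums-of-squares partition for a balanced two-way layout.
oracle_balanced_anova_ss <- function(y, A, B) {
  A <- factor(A)
  B <- factor(B)
  gm <- mean(y)
  ssa <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cell_means <- tapply(y, list(A, B), mean)
  cell_n <- tapply(y, list(A, B), length)
  a_means <- tapply(y, A, mean)
  b_means <- tapply(y, B, mean)
  inter <- outer(a_means, b_means, function(a, b) a + b) - gm
  ssab <- sum(cell_n * (cell_means - inter)^2)
  sse <- sum((y - cell_means[cbind(A, B)])^2)
  list(A = ssa, B = ssb, AB = ssab, error = sse)
}

# Small helper: hypnogram with every epoch the same state.
uniform_hypnogram <- function(state, n, ...) {
  chronosleep::hypnogram(rep(state, n), ...)
}
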