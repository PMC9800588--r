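# Independent oracles: written from first principles, sharing no code path
# with the implementation they check.

# Average ranks without rank(): r_i = #(v < v_i) + (#(v == v_i) + 1) / 2
oracle_avg_rank <- function(v) {
  vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
}

# Spearman via hand-rolled average ranks + the raw Pearson sum formula.
oracle_spearman <- function(x, y) {
  rx <- oracle_avg_rank(x)
  ry <- oracle_avg_rank(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Hypergeometric upper tail by summing point masses on the log scale.
oracle_hyper_tail <- function(overlap, term_size, deg_size, universe_size) {
  ks <- overlap:min(term_size, deg_size)
  ks <- ks[ks >= max(0, deg_size - (universe_size - term_size))]
  if (length(ks) == 0) return(0)
  sum(exp(lchoose(term_size, ks) +
            lchoose(universe_size - term_size, deg_size - ks) -
            lchoose(universe_size, deg_size)))
}

# Directed betweenness by BFS path counting: for every source s compute
# shortest-path distances d and counts sigma, then accumulate
# sigma_sv * sigma_vt / sigma_st over all pairs with d_sv + d_vt = d_st.
# `adj` is a 0/1 adjacency matrix. Normalized by (n-1)(n-2) when n > 2.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n); sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0; sigma[s, s] <- 1
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (u in frontier) {
        for (v in which(adj[u, ] == 1)) {
          if (is.infinite(d[s, v])) {
            d[s, v] <- d[s, u] + 1
            nxt <- c(nxt, v)
          }
          if (d[s, v] == d[s, u] + 1) {
            sigma[s, v] <- sigma[s, v] + sigma[s, u]
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || is.infinite(d[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t]) {
        btw[v] <- btw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2)) else btw
}

# Exact one-sided ("greater") rank-sum p by full enumeration of all
# C(n+m, n) label assignments. No ties assumed.
oracle_wilcox_greater <- function(x, y) {
  pooled <- c(x, y)
  r <- oracle_avg_rank(pooled)
  n <- length(x)
  obs <- sum(r[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(stats >= obs)
}

# BH step-up by direct application of q_i = min_{j >= i} m p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Random small digraph as an adjacency matrix (no self-loops).
random_digraph <- function(n, p_edge = 0.35) {
  adj <- matrix(as.integer(runif(n * n) < p_edge), n, n)
  diag(adj) <- 0L
  adj
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "directed")
}

# Small helper: a deterministic expression-profile pair from explicit counts.
make_profile <- function(counts, tissue = "t", phase = "estrus") {
  expression_profile(counts, tissue, phase)
}
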