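#' Load a directed signaling network from an edge list
#'
#' Accepts a 2- or 3-column table (`source`, `target`, optional sign -
#' ignored here). Multi-edges are collapsed and self-loops removed: curated
#' signaling edge lists carry no weights and centrality is computed on the
#' simple directed graph.
#'
#' @param edges Data frame (first two columns = source, target) or a path to
#'   a TSV with a header.
#' @return An igraph directed graph.
#' @export
as_signaling_network <- function(edges) {
  if (is.character(edges) && length(edges) == 1L) {
    edges <- readr::read_tsv(edges, show_col_types = FALSE)
  }
  if (igraph::is_igraph(edges)) {
    return(igraph::simplify(edges, remove.multiple = TRUE,
                            remove.loops = TRUE))
  }
  stopifnot(is.data.frame(edges), ncol(edges) >= 2L)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = TRUE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Node centralities of a directed network
#'
#' Computes, per node: total degree (in + out), directed betweenness
#' normalized by `(N - 1)(N - 2)`, and PageRank (damping 0.85, uniform
#' personalization, dangling mass redistributed uniformly). PageRank sums
#' to 1.
#'
#' @param net An igraph directed graph, edge-list data frame, or TSV path
#'   (see [as_signaling_network()]).
#' @return A `centrality_table` tibble: `node`, `degree`, `betweenness`,
#'   `pagerank`.
#' @export
compute_centralities <- function(net) {
  g <- as_signaling_network(net)
  n <- igraph::vcount(g)
  if (n == 0L) abort("network is empty.")
  btw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  if (n > 2L) btw <- btw / ((n - 1) * (n - 2))
  out <- tibble(
    node = igraph::V(g)$name %||% as.character(seq_len(n)),
    degree = as.numeric(igraph::degree(g, mode = "all")),
    betweenness = as.numeric(btw),
    pagerank = as.numeric(igraph::page_rank(g, damping = 0.85)$vector)
  )
  class(out) <- c("centrality_table", class(out))
  out
}

#' One-sided rank-sum hubness test
#'
#' Wilcoxon rank-sum test of whether DEG centralities exceed (or fall
#' below) the background: exact enumeration when `n + m <= 12` with no
#' ties, otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param deg_values Centralities of the DEG nodes.
#' @param background_values Centralities of the background (non-DEG) nodes.
#' @param alternative "greater" (DEGs more central) or "less".
#' @return A list: `p`, `statistic` (rank-sum U of the DEG sample),
#'   `degenerate` (TRUE when the pooled sample is constant, giving p = 1
#'   under "greater"/"less").
#' @export
hubness_test <- function(deg_values, background_values,
                         alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(deg_values) == 0L || length(background_values) == 0L) {
    abort("both samples must be non-empty.")
  }
  pooled <- c(deg_values, background_values)
  if (length(unique(pooled)) == 1L) {
    return(list(p = 1, statistic = NA_real_, degenerate = TRUE))
  }
  n <- length(deg_values); m <- length(background_values)
  use_exact <- (n + m <= 12L) && !anyDuplicated(pooled)
  wt <- suppressWarnings(wilcox.test(
    deg_values, background_values, alternative = alternative,
    exact = use_exact, correct = TRUE))
  list(p = wt$p.value, statistic = unname(wt$statistic), degenerate = FALSE)
}

#' Hubness report for a DEG set
#'
#' For each centrality index (degree, betweenness, PageRank), tests the DEG
#' nodes against the remaining network nodes in both directions ("greater":
#' DEGs are hubs; "less": DEGs are peripheral).
#'
#' @param centralities A [compute_centralities()] table.
#' @param deg_ids DEG ids; ids absent from the network are dropped with a
#'   message.
#' @return A tibble: `index`, `alternative`, `p`, `n_deg`, `n_background`;
#'   empty (with a warning) when no DEG maps onto the network.
#' @export
hubness_report <- function(centralities, deg_ids) {
  stopifnot(is.data.frame(centralities))
  deg_ids <- unique(deg_ids)
  mapped <- intersect(deg_ids, centralities$node)
  if (length(mapped) < length(deg_ids)) {
    inform(sprintf("hubness_report: %d DEG id(s) not in the network; dropped.",
                   length(deg_ids) - length(mapped)))
  }
  empty <- tibble(index = character(0), alternative = character(0),
                  p = numeric(0), n_deg = integer(0),
                  n_background = integer(0))
  if (length(mapped) == 0L) {
    warn("hubness_report: no DEG maps onto the network.")
    return(empty)
  }
  bg <- setdiff(centralities$node, mapped)
  if (length(bg) == 0L) {
    warn("hubness_report: DEG set covers the whole network; no background.")
    return(empty)
  }
  is_deg <- centralities$node %in% mapped
  purrr::map_dfr(c("degree", "betweenness", "pagerank"), function(idx) {
    x <- centralities[[idx]][is_deg]
    y <- centralities[[idx]][!is_deg]
    purrr::map_dfr(c("greater", "less"), function(alt) {
      tibble(index = idx, alternative = alt,
             p = hubness_test(x, y, alt)$p,
             n_deg = length(x), n_background = length(y))
    })
  })
}
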