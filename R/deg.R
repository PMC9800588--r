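#' Pooled-rate log2 fold change
#'
#' `log2(((K_a + c) / N_a) / ((K_b + c) / N_b))` with `K` the pooled
#' (replicate-summed) count, `N` the pooled library size and `c` a
#' pseudocount keeping the ratio finite at zero counts. Vectorized over
#' genes.
#'
#' @param k_a,k_b Pooled counts per gene in each condition.
#' @param n_a,n_b Pooled library sizes (> 0).
#' @param pseudocount Pseudocount `c` (default 1).
#' @return Numeric log2 fold changes.
#' @examples
#' pooled_log2fc(400, 1e6, 100, 1e6, pseudocount = 0)  # exactly 2
#' @export
pooled_log2fc <- function(k_a, n_a, k_b, n_b, pseudocount = 1) {
  if (any(k_a < 0) || any(k_b < 0)) abort("counts must be non-negative.")
  if (any(n_a <= 0) || any(n_b <= 0)) abort("library sizes must be positive.")
  log2(((k_a + pseudocount) / n_a) / ((k_b + pseudocount) / n_b))
}

#' Two-proportion z-test on pooled counts
#'
#' Tests whether a gene's pooled rate differs between conditions:
#' with pooled estimate `p = (K_a + K_b) / (N_a + N_b)`, the statistic is
#' `z = (K_a/N_a - K_b/N_b) / sqrt(p (1 - p) (1/N_a + 1/N_b))` with a
#' two-sided normal p-value. Genes with zero counts in both conditions get
#' `z = 0, p = 1`. Vectorized.
#'
#' @inheritParams pooled_log2fc
#' @return A tibble with columns `z` and `p`.
#' @export
deg_ztest <- function(k_a, n_a, k_b, n_b) {
  if (any(k_a > n_a) || any(k_b > n_b)) {
    abort("counts cannot exceed library sizes.")
  }
  if (any(k_a < 0) || any(k_b < 0)) abort("counts must be non-negative.")
  if (any(n_a <= 0) || any(n_b <= 0)) abort("library sizes must be positive.")
  phat <- (k_a + k_b) / (n_a + n_b)
  se <- sqrt(phat * (1 - phat) * (1 / n_a + 1 / n_b))
  # degenerate pooled rates (0 or 1) force equal observed rates: no signal
  z <- ifelse(se == 0, 0, (k_a / n_a - k_b / n_b) / se)
  p <- ifelse(se == 0, 1, 2 * pnorm(-abs(z)))
  tibble(z = z, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (`q_i = min_{j >= i} m p_(j) / j`), returned in
#' the input order. Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p Raw p-values in \[0, 1\].
#' @return BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Applies the DEG criterion `|log2fc| >= fc_min` and `q <= q_max` (both
#' thresholds inclusive, both conditions required) to a per-gene table,
#' adding a `call` column in \{"up", "down", "none"\}.
#'
#' @param records Data frame with columns `log2fc` and `q` (BH-adjusted).
#' @param fc_min Minimum absolute log2 fold change (default 1).
#' @param q_max Maximum q-value (default 0.05).
#' @return The input tibble with a `call` column.
#' @examples
#' call_degs(tibble::tibble(gene = "a", log2fc = 1.2, q = 0.01))$call  # "up"
#' @export
call_degs <- function(records, fc_min = 1, q_max = 0.05) {
  stopifnot(is.data.frame(records),
            all(c("log2fc", "q") %in% names(records)))
  records |>
    as_tibble() |>
    dplyr::mutate(call = dplyr::case_when(
      .data$q <= q_max & .data$log2fc >= fc_min ~ "up",
      .data$q <= q_max & .data$log2fc <= -fc_min ~ "down",
      TRUE ~ "none"
    ))
}

#' Differential expression between two phases of one tissue
#'
#' Pools replicate counts per phase, drops genes with zero pooled counts in
#' both phases (their fold change is undefined), computes the pooled-rate
#' log2 fold change (pseudocount applied to the fold change only, not the
#' test), the two-proportion z-test p-value, BH q-values across all tested
#' genes of the tissue, and the DEG call.
#'
#' @param profile_a,profile_b [expression_profile()]s of the two phases
#'   (`profile_a` is the numerator, conventionally estrus).
#' @inheritParams call_degs
#' @param pseudocount Pseudocount for the fold-change estimate.
#' @return A `deg_result` tibble: `gene`, `log2fc`, `z`, `p`, `q`, `call`,
#'   with the tissue in attribute `tissue`.
#' @export
deg_test <- function(profile_a, profile_b, fc_min = 1, q_max = 0.05,
                     pseudocount = 1) {
  stopifnot(inherits(profile_a, "expression_profile"),
            inherits(profile_b, "expression_profile"))
  shared <- intersect(rownames(profile_a$counts), rownames(profile_b$counts))
  if (length(shared) == 0L) abort("profiles share no genes.")
  ka <- rowSums(profile_a$counts[shared, , drop = FALSE])
  kb <- rowSums(profile_b$counts[shared, , drop = FALSE])
  na <- sum(profile_a$lib_sizes)
  nb <- sum(profile_b$lib_sizes)
  keep <- ka + kb > 0
  ka <- ka[keep]; kb <- kb[keep]; genes <- shared[keep]
  zt <- deg_ztest(ka, na, kb, nb)
  out <- tibble(
    gene = genes,
    log2fc = pooled_log2fc(ka, na, kb, nb, pseudocount = pseudocount),
    z = zt$z, p = zt$p, q = bh_adjust(zt$p)
  )
  out <- call_degs(out, fc_min = fc_min, q_max = q_max)
  structure(out, tissue = profile_a$tissue,
            class = c("deg_result", class(out)))
}

#' Extract the trend vector of a tissue
#'
#' Encodes each DEG's direction as +1 (up) or -1 (down); the domain is
#' exactly the DEG set of the tissue.
#'
#' @param deg_table A [deg_test()] result (or any tibble with `gene`,
#'   `call`).
#' @param tissue Tissue id (defaults to the table's attribute).
#' @return A tibble: `tissue`, `gene`, `trend` in \{+1, -1\}.
#' @export
trend_vector <- function(deg_table, tissue = NULL) {
  stopifnot(is.data.frame(deg_table),
            all(c("gene", "call") %in% names(deg_table)))
  tissue <- tissue %g% attr(deg_table, "tissue") %g% "tissue1"
  deg_table |>
    dplyr::filter(.data$call != "none") |>
    dplyr::transmute(tissue = tissue, gene = .data$gene,
                     trend = ifelse(.data$call == "up", 1, -1))
}

as_trend_map <- function(trend) {
  if (is.numeric(trend) && !is.null(names(trend))) return(trend)
  if (is.data.frame(trend) && all(c("gene", "trend") %in% names(trend))) {
    return(setNames(trend$trend, trend$gene))
  }
  abort("expected a named numeric vector or a tibble with `gene`, `trend`.")
}

#' Tissue-by-tissue cosine similarity of DEG trends
#'
#' For each tissue pair, restricts to genes called DEG in both, and takes
#' the cosine of the two +/-1 trend vectors. Pairs sharing no DEGs are
#' undefined (`NA`); the diagonal is 1.
#'
#' @param trends Stacked trend tibble (`tissue`, `gene`, `trend`), e.g.
#'   row-bound [trend_vector()] results for >= 2 tissues.
#' @return A symmetric `tissue_cosine` matrix with unit diagonal.
#' @export
tissue_cosine_matrix <- function(trends) {
  stopifnot(is.data.frame(trends),
            all(c("tissue", "gene", "trend") %in% names(trends)))
  tissues <- unique(trends$tissue)
  if (length(tissues) < 2L) abort("need trends for at least 2 tissues.")
  maps <- lapply(split(trends, trends$tissue), as_trend_map)
  m <- matrix(NA_real_, length(tissues), length(tissues),
              dimnames = list(tissues, tissues))
  diag(m) <- 1
  for (i in seq_along(tissues)) {
    for (j in seq_len(i - 1L)) {
      a <- maps[[tissues[i]]]; b <- maps[[tissues[j]]]
      shared <- intersect(names(a), names(b))
      if (length(shared) > 0L) {
        # +/-1 vectors: cosine = mean agreement minus mean disagreement
        m[i, j] <- m[j, i] <- sum(a[shared] * b[shared]) / length(shared)
      }
    }
  }
  structure(m, class = c("tissue_cosine", class(m)))
}

#' Prioritize estrous-cycle target tissues (ECTTs)
#'
#' Ranks tissues by total DEG count and keeps the top `k` (ties broken
#' lexicographically by tissue id). In the emulated design the six tissues
#' with the largest DEG burden are the estrous-cycle target tissues.
#'
#' @param deg_counts Tibble (`tissue`, `n_degs`) or named numeric vector.
#' @param k Number of tissues to keep (default 6).
#' @return Character vector of selected tissue ids, in rank order.
#' @export
select_ectts <- function(deg_counts, k = 6L) {
  if (is.numeric(deg_counts) && !is.null(names(deg_counts))) {
    deg_counts <- tibble(tissue = names(deg_counts),
                         n_degs = as.numeric(deg_counts))
  }
  stopifnot(is.data.frame(deg_counts),
            all(c("tissue", "n_degs") %in% names(deg_counts)))
  if (k > nrow(deg_counts)) abort("`k` exceeds the number of tissues.")
  ord <- order(-deg_counts$n_degs, deg_counts$tissue)
  deg_counts$tissue[ord][seq_len(k)]
}
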