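#' Signed-regulon consistency score
#'
#' Quantifies how well a trend vector supports a TF being active in a given
#' direction. For each regulon target present in the trend domain (i.e.
#' each measured DEG target): a signed edge predicts the target trend
#' `d_pred = dir_sign * edge_sign`; the score adds 1 when the observed
#' trend equals `d_pred` and subtracts 1 when it is opposite. Edges of
#' unknown direction (sign 0) add 1 for any DEG target (responsiveness
#' evidence). Targets outside the trend domain contribute nothing.
#'
#' @param regulon Tibble (`target`, `sign` in \{+1, -1, 0\}) for one TF.
#' @param trend Trend vector (tibble `gene`, `trend`, or named +/-1
#'   vector).
#' @param direction "up" or "down" (hypothesized TF activity change).
#' @return A list: `score` (integer), `n_measured` (targets in the trend
#'   domain); both `NA` with `testable = FALSE` when no target is measured.
#' @export
consistency_score <- function(regulon, trend, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(regulon),
            all(c("target", "sign") %in% names(regulon)))
  if (anyDuplicated(regulon$target)) {
    abort("regulon target ids must be unique.")
  }
  tr <- as_trend_map(trend)
  obs <- tr[regulon$target]
  measured <- !is.na(obs)
  n_meas <- sum(measured)
  if (n_meas == 0L) {
    return(list(score = NA_real_, n_measured = 0L, testable = FALSE))
  }
  dir_sign <- if (direction == "up") 1 else -1
  sgn <- regulon$sign[measured]
  obs <- obs[measured]
  pred <- dir_sign * sgn
  score <- sum(ifelse(sgn == 0, 1, (obs == pred) - (obs == -pred)))
  list(score = score, n_measured = n_meas, testable = TRUE)
}

# Score a matrix of permuted target trends (targets x B); obs_trend entries
# are +/-1 for DEGs and 0 for measured non-DEGs.
score_columns <- function(signs, trend_mat, dir_sign) {
  pred <- dir_sign * signs
  unknown <- signs == 0
  hit <- (trend_mat == pred) - (trend_mat == -pred)
  if (any(unknown)) hit[unknown, ] <- abs(trend_mat[unknown, , drop = FALSE])
  colSums(hit)
}

#' Permutation null for the consistency score
#'
#' Permutes the trend labels over the measured-gene universe `B` times
#' (holding the regulon fixed) and reports the one-sided p-value
#' `(1 + #\{S_perm >= S_obs\}) / (B + 1)`. Equivalent to sampling, for each
#' permutation, a target-sized subset of the universe-wide trend vector
#' (non-DEGs carry trend 0).
#'
#' @inheritParams consistency_score
#' @param universe Character vector of all measured genes (the permutation
#'   population); must contain the trend domain.
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @return A list: `p`, `score`, `n_measured`; `NULL` when the regulon is
#'   not testable (no measured target).
#' @export
permutation_null <- function(regulon, trend, universe,
                             direction = c("up", "down"),
                             B = 1000L, seed = 1L) {
  direction <- match.arg(direction)
  if (B < 100L) abort("`B` must be >= 100.")
  tr <- as_trend_map(trend)
  if (!all(names(tr) %in% universe)) {
    abort("trend domain must be contained in `universe`.")
  }
  obs <- consistency_score(regulon, tr, direction)
  if (!obs$testable) return(NULL)

  # universe-wide trend vector: +/-1 on DEGs, 0 elsewhere
  univ_trend <- setNames(numeric(length(universe)), universe)
  univ_trend[names(tr)] <- tr
  targets_in_univ <- intersect(regulon$target, universe)
  k <- length(targets_in_univ)
  signs <- regulon$sign[match(targets_in_univ, regulon$target)]
  dir_sign <- if (direction == "up") 1 else -1

  with_stage_seed(seed, paste0("permnull:", direction), {
    perm <- vapply(seq_len(B), function(b)
      univ_trend[sample.int(length(univ_trend), k)], numeric(k))
    perm <- matrix(perm, nrow = k)
    s_perm <- score_columns(signs, perm, dir_sign)
    p <- (1 + sum(s_perm >= obs$score)) / (B + 1)
    list(p = p, score = obs$score, n_measured = obs$n_measured)
  })
}

#' Infer directionally active transcription factors for one tissue
#'
#' Tests every regulon in both directions with the permutation null, BH-
#' adjusts across all (TF, direction) pairs of the tissue, keeps one
#' direction per TF (smaller q, ties broken by larger absolute score), and
#' flags significance at one-sided `q <= q_max`. The activity score is the
#' signed, shrunk q-value `sign(direction) * min(-log10(q), 16)`.
#'
#' @param regulons Tibble (`tf`, `target`, `sign`).
#' @param trend Trend vector of the tissue.
#' @param universe All measured genes of the tissue.
#' @param tissue Tissue id.
#' @param B Permutations per test.
#' @param seed Integer seed.
#' @param q_max One-sided significance threshold (default 0.05).
#' @return A `tf_activity` tibble: `tf`, `tissue`, `direction`, `score`,
#'   `n_measured`, `p`, `q`, `activity_score`, `significant`.
#' @export
infer_tf_activity <- function(regulons, trend, universe, tissue = "tissue1",
                              B = 1000L, seed = 1L, q_max = 0.05) {
  stopifnot(is.data.frame(regulons),
            all(c("tf", "target", "sign") %in% names(regulons)))
  tfs <- unique(regulons$tf)
  rows <- list()
  for (i in seq_along(tfs)) {
    reg <- dplyr::filter(regulons, .data$tf == tfs[i])
    for (dir in c("up", "down")) {
      res <- permutation_null(reg, trend, universe, dir, B = B,
                              seed = derive_seed(seed, paste0(tfs[i], dir)))
      if (is.null(res)) next
      rows[[paste(tfs[i], dir)]] <- tibble(
        tf = tfs[i], tissue = tissue, direction = dir,
        score = res$score, n_measured = res$n_measured, p = res$p)
    }
  }
  if (length(rows) == 0L) {
    abort("no testable regulon (no target measured in the trend domain).")
  }
  out <- dplyr::bind_rows(rows)
  out$q <- bh_adjust(out$p)
  out <- out |>
    dplyr::group_by(.data$tf) |>
    dplyr::arrange(.data$q, -abs(.data$score), .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      activity_score = ifelse(.data$direction == "up", 1, -1) *
        pmin(-log10(pmax(.data$q, 1e-16)), 16),
      significant = .data$q <= q_max
    ) |>
    dplyr::arrange(.data$tf)
  class(out) <- c("tf_activity", class(out))
  out
}

#' Select key TFs shared across target tissues
#'
#' TFs significant (either direction) in at least `min_share` of the
#' estrous-cycle target tissues; the per-tissue direction is retained (the
#' same TF may be oppositely regulated in different tissues).
#'
#' @param results Row-bound [infer_tf_activity()] results across tissues.
#' @param ectts Character vector of target-tissue ids.
#' @param min_share Minimum number of ECTTs sharing the TF (default 4).
#' @return A tibble of the selected TFs' significant rows in the ECTTs.
#' @export
key_tf_selection <- function(results, ectts, min_share = 4L) {
  stopifnot(is.data.frame(results))
  sig <- dplyr::filter(results, .data$significant, .data$tissue %in% ectts)
  keep <- sig |>
    dplyr::distinct(.data$tf, .data$tissue) |>
    dplyr::count(.data$tf) |>
    dplyr::filter(.data$n >= min_share) |>
    dplyr::pull(.data$tf)
  dplyr::filter(sig, .data$tf %in% keep) |>
    dplyr::arrange(.data$tf, .data$tissue)
}

#' Correlation between TF expression change and regulatory activity
#'
#' Spearman correlation between the significant TFs' own log2 fold change
#' (from the per-tissue DEG tables) and their signed activity scores,
#' across all significant (TF, tissue) pairs. TFs without a fold change in
#' their tissue's table are dropped with a message.
#'
#' @param results Row-bound [infer_tf_activity()] results.
#' @param deg_tables Named list (by tissue) of [deg_test()] tables.
#' @return A list: `scc`, `p`, `n_pairs`; `scc` and `p` are `NA` when fewer
#'   than 3 pairs are available.
#' @export
expression_activity_correlation <- function(results, deg_tables) {
  sig <- dplyr::filter(results, .data$significant)
  pairs <- purrr::map_dfr(seq_len(nrow(sig)), function(i) {
    tab <- deg_tables[[sig$tissue[i]]]
    if (is.null(tab)) return(NULL)
    j <- match(sig$tf[i], tab$gene)
    if (is.na(j)) return(NULL)
    tibble(log2fc = tab$log2fc[j], activity = sig$activity_score[i])
  })
  dropped <- nrow(sig) - nrow(pairs)
  if (dropped > 0) {
    inform(sprintf("expression_activity_correlation: %d TF(s) without a fold change; dropped.",
                   dropped))
  }
  if (nrow(pairs) < 3L) {
    return(list(scc = NA_real_, p = NA_real_, n_pairs = nrow(pairs)))
  }
  scc <- spearman_scc(pairs$log2fc, pairs$activity)
  list(scc = scc,
       p = if (is.na(scc)) NA_real_ else scc_pvalue(scc, nrow(pairs)),
       n_pairs = nrow(pairs))
}
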