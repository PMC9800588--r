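#' Transcriptomic alteration signature (TAS)
#'
#' A TAS is a gene-indexed log2 fold-change vector contrasting an
#' experimental state with its control, carrying a tissue of origin, an
#' outcome label ("beneficial", "deleterious" or "none") and an optional
#' 1-3 level experiment-type label path (e.g. deleterious / disease /
#' cancer). Represented as a tibble (`gene`, `log2fc`) with attributes.
#'
#' @param genes Character vector of gene ids.
#' @param values Finite numeric log2 fold changes, same length as `genes`.
#' @param id Signature identifier.
#' @param tissue Tissue of origin.
#' @param outcome One of "beneficial", "deleterious", "none".
#' @param label_path Character vector of hierarchical labels (level 1 is the
#'   outcome).
#' @param phase Phase of the contrast's numerator, for phase-coupled
#'   simulations (default "estrus").
#' @return A `tas` tibble.
#' @export
tas <- function(genes, values, id, tissue = "unknown",
                outcome = c("none", "beneficial", "deleterious"),
                label_path = character(0), phase = "estrus") {
  outcome <- match.arg(outcome)
  if (length(genes) != length(values)) {
    abort("`genes` and `values` must have the same length.")
  }
  if (!all(is.finite(values))) abort("TAS values must be finite.")
  if (anyDuplicated(genes)) abort("TAS gene ids must be unique.")
  out <- tibble(gene = as.character(genes), log2fc = as.numeric(values))
  structure(out, id = id, tissue = tissue, outcome = outcome,
            label_path = as.character(label_path), phase = phase,
            class = c("tas", class(out)))
}

as_tas <- function(x) {
  if (inherits(x, "tas")) return(x)
  if (is.data.frame(x) && all(c("gene", "log2fc") %in% names(x))) {
    return(tas(x$gene, x$log2fc, id = "query"))
  }
  abort("expected a `tas` or a data frame with columns `gene`, `log2fc`.")
}

tas_id <- function(x) attr(x, "id") %g% "query"
tas_tissue <- function(x) attr(x, "tissue") %g% "unknown"
tas_outcome <- function(x) attr(x, "outcome") %g% "none"
tas_label_path <- function(x) attr(x, "label_path") %g% character(0)

#' @export
print.tas <- function(x, ...) {
  cat(sprintf("<tas> %s (%s, %s): %d genes\n", tas_id(x), tas_tissue(x),
              tas_outcome(x), nrow(x)))
  NextMethod()
}

#' TAS library
#'
#' A collection of [tas()] members plus a metadata table (`id`, `tissue`,
#' `outcome`, slash-separated `label_path`).
#'
#' @param members List of [tas()] objects.
#' @return A `tas_library` object.
#' @export
tas_library <- function(members) {
  ids <- unname(vapply(members, tas_id, character(1)))
  if (anyDuplicated(ids)) abort("library member ids must be unique.")
  names(members) <- ids
  meta <- tibble(
    id = ids,
    tissue = unname(vapply(members, tas_tissue, character(1))),
    outcome = unname(vapply(members, tas_outcome, character(1))),
    label_path = unname(vapply(members, function(m)
      paste(tas_label_path(m), collapse = "/"), character(1)))
  )
  structure(list(members = members, meta = meta), class = "tas_library")
}

#' @export
print.tas_library <- function(x, ...) {
  cat(sprintf("<tas_library> %d members across %d tissue(s)\n",
              length(x$members), dplyr::n_distinct(x$meta$tissue)))
  invisible(x)
}

#' @export
length.tas_library <- function(x) length(x$members)

#' Build a TAS from two expression profiles
#'
#' Computes the per-gene pooled-rate log2 fold change of `profile_a` over
#' `profile_b` (replicate counts summed, rates = pooled count / pooled
#' library size, pseudocount added to pooled counts). Genes with zero pooled
#' counts in both profiles are dropped: their fold change is undefined.
#'
#' @param profile_a,profile_b [expression_profile()]s sharing a gene
#'   universe; `profile_a` is the numerator phase (e.g. estrus, giving the
#'   estrus-induced TAS when `profile_b` is diestrus).
#' @param pseudocount Added to pooled counts before forming rates.
#' @param id Signature id (defaults to "<tissue>_<phaseA>_vs_<phaseB>").
#' @return A [tas()].
#' @export
build_tas <- function(profile_a, profile_b, pseudocount = 1, id = NULL) {
  stopifnot(inherits(profile_a, "expression_profile"),
            inherits(profile_b, "expression_profile"))
  shared <- intersect(rownames(profile_a$counts), rownames(profile_b$counts))
  if (length(shared) == 0L) abort("profiles share no genes.")
  ka <- rowSums(profile_a$counts[shared, , drop = FALSE])
  kb <- rowSums(profile_b$counts[shared, , drop = FALSE])
  keep <- ka + kb > 0
  lfc <- pooled_log2fc(ka[keep], sum(profile_a$lib_sizes),
                       kb[keep], sum(profile_b$lib_sizes),
                       pseudocount = pseudocount)
  id <- id %g% sprintf("%s_%s_vs_%s", profile_a$tissue, profile_a$phase,
                       profile_b$phase)
  tas(shared[keep], lfc, id = id, tissue = profile_a$tissue,
      phase = profile_a$phase)
}

#' Spearman correlation coefficient
#'
#' Rank correlation: the Pearson correlation of average-ranked values (ties
#' get their mean rank).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return The SCC in \[-1, 1\], or `NA` when either vector has zero rank
#'   variance (constant input), for which no correlation is defined.
#' @examples
#' spearman_scc(1:10, (1:10)^3)  # 1: invariant to monotone transforms
#' @export
spearman_scc <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 3L) abort("need at least 3 paired observations.")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::var(rx) == 0 || stats::var(ry) == 0) return(NA_real_)
  cor(rx, ry, method = "pearson")
}

#' Analytic p-value for a Spearman correlation
#'
#' Two-sided p-value from the t approximation
#' `t = scc * sqrt((n - 2) / (1 - scc^2))` on `n - 2` degrees of freedom,
#' standard at transcriptome-scale n. `|scc| = 1` maps to p = 0.
#'
#' @param scc Spearman correlation(s).
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value(s).
#' @export
scc_pvalue <- function(scc, n) {
  if (any(n < 3L)) abort("`n` must be >= 3.")
  p <- ifelse(abs(scc) >= 1, 0,
              2 * pt(abs(scc) * sqrt((n - 2) / (1 - scc^2)),
                     df = n - 2, lower.tail = FALSE))
  ifelse(is.na(scc), NA_real_, p)
}

scc_pair <- function(a, b, min_overlap) {
  shared <- intersect(a$gene, b$gene)
  if (length(shared) < min_overlap) return(NULL)
  va <- a$log2fc[match(shared, a$gene)]
  vb <- b$log2fc[match(shared, b$gene)]
  list(n = length(shared), scc = spearman_scc(va, vb))
}

#' Remove redundant library members
#'
#' Greedy pass in library (curation) order, per tissue: a member is retained
#' iff its SCC with every already-retained member of the same tissue is
#' below `scc_cut`. Pairs sharing fewer than `min_overlap` genes are treated
#' as non-redundant. Deterministic by construction.
#'
#' @param library A [tas_library()].
#' @param scc_cut Redundancy cutoff (members at SCC >= cut are dropped).
#' @param min_overlap Minimum shared genes for an SCC to count.
#' @return The pruned [tas_library()].
#' @export
prune_redundant <- function(library, scc_cut = 0.5, min_overlap = 100L) {
  stopifnot(inherits(library, "tas_library"))
  keep <- character(0)
  by_tissue <- split(library$meta$id, library$meta$tissue)
  for (ids in by_tissue) {
    retained <- character(0)
    for (id in ids) {
      m <- library$members[[id]]
      redundant <- FALSE
      for (r in retained) {
        pr <- scc_pair(m, library$members[[r]], min_overlap)
        # 1e-12 slack keeps the inclusive boundary robust to floating-point
        # rank arithmetic
        if (!is.null(pr) && !is.na(pr$scc) && pr$scc >= scc_cut - 1e-12) {
          redundant <- TRUE
          break
        }
      }
      if (!redundant) retained <- c(retained, id)
    }
    keep <- c(keep, retained)
  }
  # preserve original library order
  keep <- library$meta$id[library$meta$id %in% keep]
  tas_library(library$members[keep])
}

#' Match a query TAS against a library
#'
#' Computes the SCC between the query and every same-tissue library member
#' over their gene intersection, with the analytic p-value from
#' [scc_pvalue()]. A member is a significant hit when `|SCC| >=
#' scc_threshold`; pairs sharing fewer than `min_overlap` genes are skipped
#' (reported via a message).
#'
#' @param query A [tas()] (e.g. the estrus-induced signature).
#' @param library A [tas_library()].
#' @param scc_threshold Hit threshold on |SCC|.
#' @param min_overlap Minimum shared genes.
#' @return A tibble of correlation hits: `query_id`, `library_id`, `tissue`,
#'   `n_shared`, `scc`, `p`, `significant`, `outcome`, `label_path`.
#' @export
match_library <- function(query, library, scc_threshold = 0.1,
                          min_overlap = 100L) {
  query <- as_tas(query)
  stopifnot(inherits(library, "tas_library"))
  meta <- dplyr::filter(library$meta, .data$tissue == tas_tissue(query))
  if (nrow(meta) == 0L) {
    warn(sprintf("no library members for tissue '%s'.", tas_tissue(query)))
    return(tibble(query_id = character(0), library_id = character(0),
                  tissue = character(0), n_shared = integer(0),
                  scc = numeric(0), p = numeric(0),
                  significant = logical(0), outcome = character(0),
                  label_path = character(0)))
  }
  skipped <- 0L
  rows <- purrr::map(meta$id, function(id) {
    pr <- scc_pair(query, library$members[[id]], min_overlap)
    if (is.null(pr)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    tibble(query_id = tas_id(query), library_id = id,
           tissue = tas_tissue(query), n_shared = pr$n,
           scc = pr$scc, p = scc_pvalue(pr$scc, pr$n),
           # inclusive boundary, robust to floating-point rank arithmetic
           significant = !is.na(pr$scc) &
             abs(pr$scc) >= scc_threshold - 1e-12)
  })
  if (skipped > 0L) {
    inform(sprintf("match_library: skipped %d member(s) below min_overlap = %d.",
                   skipped, min_overlap))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::left_join(out, meta[, c("id", "outcome", "label_path")],
                   by = c(library_id = "id"))
}

#' Aggregate correlation hits into a phase-protection call
#'
#' Each significant hit with a non-"none" outcome votes: the query phase is
#' protective iff the hit correlates positively with a beneficial state or
#' negatively with a deleterious one; otherwise it votes harmful. The
#' verdict is by majority (for an estrus-induced query: "estrus-protective"
#' vs "diestrus-protective"; ties or no votes give "indeterminate"), with a
#' two-sided exact binomial sign test against an even split. Reproductive
#' tissues (ovary, uterus) are excluded by default because correlated
#' deleterious signatures there may reflect ordinary physiological
#' differences between phases rather than harm.
#'
#' @param hits Tibble from [match_library()], possibly several tissues.
#' @param include_reproductive Keep ovary/uterus verdicts (default FALSE).
#' @param reproductive_tissues Tissue ids treated as reproductive.
#' @return A `ptsp_result` tibble: `tissue`, `protective_votes`,
#'   `harmful_votes`, `verdict`, `sign_test_p`.
#' @export
ptsp_aggregate <- function(hits, include_reproductive = FALSE,
                           reproductive_tissues = c("ovary", "uterus")) {
  stopifnot(is.data.frame(hits))
  if (!include_reproductive) {
    hits <- dplyr::filter(hits, !.data$tissue %in% reproductive_tissues)
  }
  voting <- dplyr::filter(hits, .data$significant,
                          .data$outcome %in% c("beneficial", "deleterious"))
  out <- voting |>
    dplyr::mutate(protective = (.data$scc > 0 & .data$outcome == "beneficial") |
                    (.data$scc < 0 & .data$outcome == "deleterious")) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(
      protective_votes = sum(.data$protective),
      harmful_votes = sum(!.data$protective),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      verdict = dplyr::case_when(
        protective_votes > harmful_votes ~ "estrus-protective",
        harmful_votes > protective_votes ~ "diestrus-protective",
        TRUE ~ "indeterminate"
      ),
      sign_test_p = purrr::map2_dbl(
        .data$protective_votes, .data$harmful_votes,
        function(a, b) {
          if (a + b == 0) return(NA_real_)
          binom.test(a, a + b, p = 0.5)$p.value
        })
    )
  # tissues present in hits but with zero votes are indeterminate
  silent <- setdiff(unique(hits$tissue), out$tissue)
  if (length(silent) > 0) {
    out <- dplyr::bind_rows(out, tibble(
      tissue = silent, protective_votes = 0L, harmful_votes = 0L,
      verdict = "indeterminate", sign_test_p = NA_real_))
  }
  out <- dplyr::arrange(out, .data$tissue)
  class(out) <- c("ptsp_result", class(out))
  out
}

#' Hierarchical label counts for correlated signatures
#'
#' Counts library members per label-path prefix (every ancestor of a path
#' counts its descendants), separately for positively correlated hits,
#' negatively correlated hits and the full library background — the counts
#' behind a sunburst-style display.
#'
#' @param hits Tibble from [match_library()].
#' @param library The matched [tas_library()] (background).
#' @return A tibble: `group` ("positive", "negative", "background"),
#'   `prefix` (slash-joined), `depth`, `n`.
#' @export
label_hierarchy_summary <- function(hits, library) {
  stopifnot(inherits(library, "tas_library"))
  count_paths <- function(paths, group) {
    paths <- paths[nzchar(paths)]
    if (length(paths) == 0L) {
      return(tibble(group = character(0), prefix = character(0),
                    depth = integer(0), n = integer(0)))
    }
    prefixes <- unlist(lapply(strsplit(paths, "/", fixed = TRUE),
                              function(p) vapply(seq_along(p), function(d)
                                paste(p[seq_len(d)], collapse = "/"),
                                character(1))))
    tab <- table(prefixes)
    tibble(group = group, prefix = names(tab),
           depth = lengths(strsplit(names(tab), "/", fixed = TRUE)),
           n = as.integer(tab))
  }
  sig <- dplyr::filter(hits, .data$significant)
  dplyr::bind_rows(
    count_paths(sig$label_path[sig$scc > 0], "positive"),
    count_paths(sig$label_path[sig$scc < 0], "negative"),
    count_paths(library$meta$label_path, "background")
  )
}
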