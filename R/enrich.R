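#' Read a GMT gene-set collection
#'
#' Standard tab-delimited GMT (set id, description, member genes...).
#' Parsing is delegated to fgsea when available, with a minimal fallback.
#'
#' @param path Path to a .gmt file.
#' @param collection Collection label attached to every set (e.g. "KEGG",
#'   "Hallmark", "GAD", "custom").
#' @return A tibble: `id`, `name`, `collection`, `members` (list column).
#' @export
read_gmt <- function(path, collection = "custom") {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  bad <- which(lengths(lines) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed GMT line %d in '%s' (fewer than 3 fields).",
                  bad[1], path))
  }
  members <- if (requireNamespace("fgsea", quietly = TRUE)) {
    unname(lapply(fgsea::gmtPathways(path), unique))
  } else {
    lapply(lines, function(x) unique(x[-(1:2)]))
  }
  tibble(
    id = vapply(lines, `[`, character(1), 1),
    name = vapply(lines, `[`, character(1), 2),
    collection = collection,
    members = members
  )
}

#' Write a GMT file
#'
#' @param genesets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(genesets, path) {
  lines <- vapply(seq_len(nrow(genesets)), function(i) {
    paste(c(genesets$id[i], genesets$name[i], genesets$members[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' One-sided Fisher enrichment test
#'
#' Over-representation of a gene set within a DEG set, both restricted to a
#' gene universe: the hypergeometric upper tail `P(X >= overlap)` of the
#' 2x2 table.
#'
#' @param deg_set Character vector of DEG ids (subset of the universe; ids
#'   outside are dropped).
#' @param term Character vector of gene-set members.
#' @param universe Background gene ids (all genes tested for differential
#'   expression).
#' @return A list with `overlap` and `p`.
#' @examples
#' fisher_enrich(letters[1:5], letters[1:5], letters[1:20])$p  # 1/choose(20,5)
#' @export
fisher_enrich <- function(deg_set, term, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("`universe` must be non-empty.")
  deg_set <- intersect(unique(deg_set), universe)
  term <- intersect(unique(term), universe)
  overlap <- length(intersect(deg_set, term))
  # P(X >= overlap) with X ~ Hypergeom(|term| white, |U|-|term| black, |deg| drawn)
  p <- phyper(overlap - 1L, length(term), length(universe) - length(term),
              length(deg_set), lower.tail = FALSE)
  list(overlap = overlap, p = p)
}

#' Over-representation analysis across tissues and directions
#'
#' For every tissue, tests each gene set against the up-regulated DEGs, the
#' down-regulated DEGs and their union ("both"), with BH correction within
#' each tissue x collection x direction family and significance at
#' `q <= q_max`. DEG ids absent from the tissue's universe are dropped with
#' a message.
#'
#' @param trends Stacked trend tibble (`tissue`, `gene`, `trend`).
#' @param genesets Gene-set tibble from [read_gmt()] (or built in code).
#' @param universe Character vector of background genes, or a named list of
#'   per-tissue universes (all genes tested in that tissue).
#' @param q_max Significance threshold on the q-value.
#' @return An `enrichment_result` tibble: `term`, `name`, `collection`,
#'   `tissue`, `direction`, `overlap`, `overlap_genes` (list), `p`, `q`,
#'   `significant`.
#' @export
run_enrichment <- function(trends, genesets, universe, q_max = 0.05) {
  stopifnot(is.data.frame(trends), is.data.frame(genesets))
  tissues <- unique(trends$tissue)
  get_universe <- function(t) {
    u <- if (is.list(universe)) universe[[t]] else universe
    if (is.null(u)) abort(sprintf("no universe for tissue '%s'.", t))
    unique(u)
  }
  rows <- list()
  for (t in tissues) {
    tr <- dplyr::filter(trends, .data$tissue == t)
    u <- get_universe(t)
    dropped <- sum(!tr$gene %in% u)
    if (dropped > 0) {
      inform(sprintf("run_enrichment: %d DEG id(s) of '%s' absent from the universe; dropped.",
                     dropped, t))
      tr <- dplyr::filter(tr, .data$gene %in% u)
    }
    sets_by_dir <- list(up = tr$gene[tr$trend > 0],
                        down = tr$gene[tr$trend < 0],
                        both = tr$gene)
    for (dir in names(sets_by_dir)) {
      ds <- sets_by_dir[[dir]]
      if (length(ds) == 0L) next
      res <- purrr::map(seq_len(nrow(genesets)), function(i) {
        fe <- fisher_enrich(ds, genesets$members[[i]], u)
        tibble(term = genesets$id[i], name = genesets$name[i],
               collection = genesets$collection[i], tissue = t,
               direction = dir, overlap = fe$overlap,
               overlap_genes = list(intersect(ds, genesets$members[[i]])),
               p = fe$p)
      })
      rows[[paste(t, dir)]] <- dplyr::bind_rows(res)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble(term = character(0), name = character(0),
                  collection = character(0), tissue = character(0),
                  direction = character(0), overlap = integer(0),
                  overlap_genes = list(), p = numeric(0))
  }
  out <- out |>
    dplyr::group_by(.data$tissue, .data$collection, .data$direction) |>
    dplyr::mutate(q = bh_adjust(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$q <= q_max)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Terms significant in at least `min_tissues` tissues
#'
#' A term qualifies when it is significant (any direction) in at least
#' `min_tissues` distinct tissues.
#'
#' @param results An [run_enrichment()] result.
#' @param min_tissues Minimum number of distinct tissues (default 5).
#' @return Character vector of qualifying term ids.
#' @export
shared_terms <- function(results, min_tissues = 5L) {
  stopifnot(is.data.frame(results))
  results |>
    dplyr::filter(.data$significant) |>
    dplyr::distinct(.data$term, .data$tissue) |>
    dplyr::count(.data$term) |>
    dplyr::filter(.data$n >= min_tissues) |>
    dplyr::pull(.data$term)
}

#' Link term pairs by DEG-set overlap
#'
#' Two terms are linked when their contributing DEG sets overlap by at
#' least `min_frac` of the smaller set:
#' `|A intersect B| / min(|A|, |B|) >= min_frac`.
#'
#' @param term_genes Named list: per term, the union of its contributing
#'   DEGs across tissues.
#' @param min_frac Overlap fraction threshold (default 0.25).
#' @return A tibble: `term1`, `term2`, `overlap_frac`, `linked`.
#' @export
term_overlap_links <- function(term_genes, min_frac = 0.25) {
  stopifnot(is.list(term_genes))
  ids <- names(term_genes)
  if (length(ids) < 2L) {
    return(tibble(term1 = character(0), term2 = character(0),
                  overlap_frac = numeric(0), linked = logical(0)))
  }
  pairs <- utils::combn(ids, 2L)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- unique(term_genes[[pairs[1, k]]])
    b <- unique(term_genes[[pairs[2, k]]])
    frac <- if (min(length(a), length(b)) == 0L) 0 else
      length(intersect(a, b)) / min(length(a), length(b))
    tibble(term1 = pairs[1, k], term2 = pairs[2, k],
           overlap_frac = frac, linked = frac >= min_frac)
  })
}
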