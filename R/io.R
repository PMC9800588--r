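# TSV readers/writers for the pipeline's external formats. All files are
# plain tab-separated text with headers.

#' Write / read a pair of phase profiles as a count matrix TSV
#'
#' Columns are sample ids `TISSUE_PHASE_repN`; rows are genes (first column
#' `gene`).
#'
#' @param profiles List with elements `estrus` and `diestrus`
#'   ([expression_profile()]s).
#' @param path Output TSV path.
#' @return `path` invisibly (writer); profile list (reader).
#' @export
write_counts_tsv <- function(profiles, path) {
  m <- cbind(profiles$estrus$counts, profiles$diestrus$counts)
  df <- dplyr::bind_cols(tibble(gene = rownames(m)), as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  parts <- strsplit(colnames(m), "_", fixed = TRUE)
  tissue <- vapply(parts, `[`, character(1), 1)
  phase <- vapply(parts, `[`, character(1), 2)
  stopifnot(length(unique(tissue)) == 1L)
  lapply(split(seq_len(ncol(m)), phase), function(idx) {
    expression_profile(m[, idx, drop = FALSE], tissue[1], phase[idx[1]])
  })
}

#' Read a signed regulon table
#'
#' TSV with columns `tf`, `target`, `sign` (+1, -1, or 0 for regulation of
#' unknown direction).
#'
#' @param path TSV path.
#' @return A tibble (`tf`, `target`, `sign`).
#' @export
read_regulons_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          tf = readr::col_character(),
                          target = readr::col_character(),
                          sign = readr::col_double()))
  if (!all(df$sign %in% c(-1, 0, 1))) {
    abort("regulon signs must be -1, 0 or +1.")
  }
  df
}

#' Write a network as a 3-column edge-list TSV
#'
#' @param net igraph graph.
#' @param path TSV path.
#' @export
write_network_tsv <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  readr::write_tsv(tibble(source = el$from, target = el$to, sign = 1),
                   path)
  invisible(path)
}

#' Write / read a TAS library (one values TSV per member + a metadata TSV)
#'
#' The metadata TSV has columns `id`, `tissue`, `outcome`, `label_path`
#' (slash-separated); each member TSV has columns `gene`, `log2fc`.
#'
#' @param library A [tas_library()].
#' @param dir Directory for the member TSVs and `metadata.tsv`.
#' @return `dir` invisibly (writer); a [tas_library()] (reader).
#' @export
write_tas_library <- function(library, dir) {
  stopifnot(inherits(library, "tas_library"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(library$meta, file.path(dir, "metadata.tsv"))
  for (id in names(library$members)) {
    readr::write_tsv(as_tibble(library$members[[id]]),
                     file.path(dir, paste0(id, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_tas_library
#' @export
read_tas_library <- function(dir) {
  meta <- readr::read_tsv(file.path(dir, "metadata.tsv"),
                          show_col_types = FALSE)
  meta$label_path <- as.character(meta$label_path)
  members <- lapply(seq_len(nrow(meta)), function(i) {
    df <- readr::read_tsv(file.path(dir, paste0(meta$id[i], ".tsv")),
                          show_col_types = FALSE)
    tas(df$gene, df$log2fc, id = meta$id[i], tissue = meta$tissue[i],
        outcome = meta$outcome[i],
        label_path = strsplit(meta$label_path[i], "/", fixed = TRUE)[[1]])
  })
  tas_library(members)
}

#' Apply a gene-ortholog mapping to a DEG or trend table
#'
#' Replaces gene ids by their orthologs (e.g. mouse to human) after DEG
#' calling; unmapped genes are dropped with a message, and many-to-one
#' collisions keep the first occurrence.
#'
#' @param tab Tibble with a `gene` column.
#' @param mapping Tibble with columns `from`, `to`, or a TSV path.
#' @return The table with mapped `gene` ids.
#' @export
apply_ortholog_map <- function(tab, mapping) {
  if (is.character(mapping) && length(mapping) == 1L) {
    mapping <- readr::read_tsv(mapping, show_col_types = FALSE)
  }
  stopifnot(all(c("from", "to") %in% names(mapping)))
  idx <- match(tab$gene, mapping$from)
  dropped <- sum(is.na(idx))
  if (dropped > 0) {
    inform(sprintf("apply_ortholog_map: %d unmapped gene(s) dropped.", dropped))
  }
  out <- tab[!is.na(idx), , drop = FALSE]
  out$gene <- mapping$to[idx[!is.na(idx)]]
  out[!duplicated(out$gene), , drop = FALSE]
}
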