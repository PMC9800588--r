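# broom-style tidiers for the result classes.

#' Tidy / summarize a differential-expression result
#'
#' `tidy()` returns the per-gene table with an explicit `tissue` column;
#' `glance()` a one-row summary (genes tested, up/down calls).
#'
#' @param x A [deg_test()] result.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.deg_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "deg_result")
  dplyr::bind_cols(tibble(tissue = attr(x, "tissue") %g% NA_character_), out)
}

#' @rdname tidy.deg_result
#' @export
glance.deg_result <- function(x, ...) {
  tibble(tissue = attr(x, "tissue") %g% NA_character_,
         n_genes = nrow(x),
         n_up = sum(x$call == "up"),
         n_down = sum(x$call == "down"))
}

#' Tidy / summarize a TF-activity result
#'
#' @param x An [infer_tf_activity()] result.
#' @param ... Unused.
#' @return A tibble; `glance()` gives one row per tissue with the number of
#'   significant TFs and the strongest activity score.
#' @export
tidy.tf_activity <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "tf_activity")
  out
}

#' @rdname tidy.tf_activity
#' @export
glance.tf_activity <- function(x, ...) {
  as_tibble(x) |>
    dplyr::group_by(.data$tissue) |>
    dplyr::summarise(n_tested = dplyr::n(),
                     n_significant = sum(.data$significant),
                     max_abs_activity = max(abs(.data$activity_score)),
                     .groups = "drop")
}

#' Tidy / summarize a PTSP result
#'
#' @param x A [ptsp_aggregate()] result.
#' @param ... Unused.
#' @return A tibble; `glance()` counts tissues per verdict.
#' @export
tidy.ptsp_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "ptsp_result")
  out
}

#' @rdname tidy.ptsp_result
#' @export
glance.ptsp_result <- function(x, ...) {
  tibble(n_tissues = nrow(x),
         n_estrus_protective = sum(x$verdict == "estrus-protective"),
         n_diestrus_protective = sum(x$verdict == "diestrus-protective"),
         n_indeterminate = sum(x$verdict == "indeterminate"))
}

#' Tidy a tissue cosine-similarity matrix into long form
#'
#' @param x A [tissue_cosine_matrix()] result.
#' @param ... Unused.
#' @return A tibble: `tissue1`, `tissue2`, `cosine` (NA where the pair
#'   shares no DEGs).
#' @export
tidy.tissue_cosine <- function(x, ...) {
  m <- unclass(x)
  tibble(
    tissue1 = rep(rownames(m), times = ncol(m)),
    tissue2 = rep(colnames(m), each = nrow(m)),
    cosine = as.vector(m)
  )
}

#' Tidy an enrichment result (drops the list column)
#'
#' @param x A [run_enrichment()] result.
#' @param ... Unused.
#' @return A tibble without the `overlap_genes` list column.
#' @export
tidy.enrichment_result <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "enrichment_result")
  out$overlap_genes <- NULL
  out
}
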