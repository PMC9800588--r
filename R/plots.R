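# ggplot2 displays for the result classes.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_point geom_col
#'   geom_hline geom_vline scale_fill_gradient2 labs theme_minimal facet_wrap
#'   coord_flip
NULL

#' @export
ggplot2::autoplot

#' Heatmap of tissue trend cosine similarities
#'
#' @param object A [tissue_cosine_matrix()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tissue_cosine <- function(object, ...) {
  df <- tidy.tissue_cosine(object)
  ggplot(df, aes(x = .data$tissue1, y = .data$tissue2,
                 fill = .data$cosine)) +
    geom_tile() +
    scale_fill_gradient2(limits = c(-1, 1), low = "#2166AC",
                         mid = "white", high = "#B2182B", na.value = "grey80") +
    labs(x = NULL, y = NULL, fill = "cosine",
         title = "Shared-DEG trend similarity between tissues") +
    theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object A [deg_test()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.deg_result <- function(object, ...) {
  df <- tidy.deg_result(object)
  ggplot(df, aes(x = .data$log2fc, y = -log10(pmax(.data$q, 1e-300)),
                 colour = .data$call)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_vline(xintercept = c(-1, 1), linetype = 2, linewidth = 0.3) +
    geom_hline(yintercept = -log10(0.05), linetype = 2, linewidth = 0.3) +
    labs(x = "log2 fold change (estrus vs diestrus)", y = "-log10 q",
         colour = NULL, title = attr(object, "tissue")) +
    theme_minimal()
}

#' Significance grid of an enrichment result
#'
#' Term-by-tissue tiles, faceted by direction (up / down / both), shaded by
#' -log10 q for significant cells.
#'
#' @param object A [run_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tidy.enrichment_result(object)
  df$shade <- ifelse(df$significant, -log10(pmax(df$q, 1e-16)), NA_real_)
  ggplot(df, aes(x = .data$tissue, y = .data$term, fill = .data$shade)) +
    geom_tile(colour = "grey90") +
    facet_wrap(~direction) +
    scale_fill_gradient2(low = "white", high = "#B2182B",
                         na.value = "white") +
    labs(x = NULL, y = NULL, fill = "-log10 q",
         title = "Over-represented terms by tissue and direction") +
    theme_minimal()
}

#' Activity scores of inferred TFs
#'
#' @param object An [infer_tf_activity()] result (one or more tissues).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tf_activity <- function(object, ...) {
  df <- tidy.tf_activity(object)
  ggplot(df, aes(x = stats::reorder(.data$tf, .data$activity_score),
                 y = .data$activity_score, fill = .data$significant)) +
    geom_col() +
    coord_flip() +
    facet_wrap(~tissue) +
    labs(x = NULL, y = "signed activity score (capped -log10 q)",
         fill = "q <= 0.05",
         title = "Transcription-factor activity (estrus vs diestrus)") +
    theme_minimal()
}

#' Protective / harmful vote counts per tissue
#'
#' @param object A [ptsp_aggregate()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ptsp_result <- function(object, ...) {
  df <- tidy.ptsp_result(object) |>
    tidyr::pivot_longer(c("protective_votes", "harmful_votes"),
                        names_to = "vote", values_to = "n")
  ggplot(df, aes(x = .data$tissue, y = .data$n, fill = .data$vote)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "significant correlated signatures",
         fill = NULL, title = "Phase-to-tissue protection votes") +
    theme_minimal()
}
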