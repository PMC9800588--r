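#' Pipeline configuration
#'
#' Thresholds and sampling parameters for [run_pipeline()], mirroring the
#' analysis order DEG -> enrichment -> network hubness -> TF activity ->
#' TAS comparison.
#'
#' @param fc_min,q_max DEG criterion: `|log2fc| >= fc_min` and
#'   `q <= q_max`.
#' @param scc_threshold TAS match threshold on |SCC|.
#' @param redundancy_cut Library redundancy cutoff (SCC).
#' @param min_overlap Minimum shared genes for an SCC.
#' @param min_tissues Shared-term rule for enrichment reporting.
#' @param min_share Key-TF rule (significant in >= `min_share` ECTTs).
#' @param k_ectts Number of estrous-cycle target tissues.
#' @param B Permutations for the TF null.
#' @param seed Master seed; every stochastic stage draws a derived
#'   substream.
#' @param include_reproductive Include ovary/uterus in PTSP verdicts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fc_min = 1, q_max = 0.05, scc_threshold = 0.1,
                            redundancy_cut = 0.5, min_overlap = 100L,
                            min_tissues = 5L, min_share = 4L, k_ectts = 6L,
                            B = 1000L, seed = 1L,
                            include_reproductive = FALSE) {
  for (nm in c("fc_min", "q_max", "scc_threshold", "redundancy_cut",
               "min_overlap", "min_tissues", "min_share", "k_ectts", "B")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm),
            class = "estrocycle_invalid_config")
    }
  }
  structure(list(fc_min = fc_min, q_max = q_max,
                 scc_threshold = scc_threshold,
                 redundancy_cut = redundancy_cut,
                 min_overlap = as.integer(min_overlap),
                 min_tissues = as.integer(min_tissues),
                 min_share = as.integer(min_share),
                 k_ectts = as.integer(k_ectts), B = as.integer(B),
                 seed = as.integer(seed),
                 include_reproductive = include_reproductive),
            class = "pipeline_config")
}

#' Validate gene-id consistency of a study bundle
#'
#' Report-only check of id overlap between the count universe and the
#' network, regulons and TAS libraries; low overlaps are flagged as
#' warnings in the report (not conditions).
#'
#' @param study A bundle as produced by [simulate_study()].
#' @return A tibble: `component`, `n_ids`, `overlap_fraction`, `warning`.
#' @export
validate_inputs <- function(study) {
  genes <- unique(unlist(lapply(study$profiles, function(p)
    rownames(p$estrus$counts))))
  frac <- function(ids) {
    ids <- unique(ids)
    if (length(ids) == 0L) return(c(0L, NA_real_))
    c(length(ids), mean(ids %in% genes))
  }
  comps <- list(
    network = igraph::V(as_signaling_network(study$network))$name,
    regulon_targets = study$regulons$target,
    tas_library = unlist(lapply(study$libraries, function(l)
      unique(unlist(lapply(l$members, function(m) m$gene)))))
  )
  out <- purrr::imap_dfr(comps, function(ids, nm) {
    f <- frac(ids)
    tibble(component = nm, n_ids = as.integer(f[1]), overlap_fraction = f[2])
  })
  out$warning <- !is.na(out$overlap_fraction) & out$overlap_fraction < 0.5
  out
}

#' Run the full analysis pipeline on a study bundle
#'
#' Executes, in order: per-tissue DEG calling and trend encoding; tissue
#' cosine clustering and ECTT prioritization; over-representation analysis
#' (when gene sets are supplied); network centralities and per-tissue
#' hubness tests; per-tissue TF activity inference with key-TF selection
#' and the expression-activity correlation; and per-tissue TAS library
#' pruning, matching and PTSP aggregation. Identical study + config give
#' identical results.
#'
#' @param study Bundle with `profiles` (per tissue: `estrus`, `diestrus`),
#'   and optionally `network`, `regulons`, `libraries`, `genesets` (see
#'   [simulate_study()]).
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `deg_tables`, `trends`, `deg_counts`,
#'   `cosine`, `ectts`, `enrichment`, `shared`, `centralities`, `hubness`,
#'   `tf_activity`, `key_tfs`, `expr_activity`, `hits`, `ptsp`, `labels`,
#'   `manifest`.
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  tissues <- names(study$profiles)
  if (length(tissues) == 0L) abort("study has no profiles.")
  if (config$k_ectts > length(tissues)) {
    abort("`k_ectts` exceeds the number of tissues.",
          class = "estrocycle_invalid_config")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)), parent = e)
    })
  }

  # --- differential expression ---------------------------------------------
  res <- stage("deg", {
    deg_tables <- lapply(tissues, function(t) {
      deg_test(study$profiles[[t]]$estrus, study$profiles[[t]]$diestrus,
               fc_min = config$fc_min, q_max = config$q_max)
    })
    names(deg_tables) <- tissues
    trends <- dplyr::bind_rows(lapply(tissues, function(t)
      trend_vector(deg_tables[[t]], tissue = t)))
    deg_counts <- trends |> dplyr::count(.data$tissue, name = "n_degs") |>
      dplyr::right_join(tibble(tissue = tissues), by = "tissue") |>
      dplyr::mutate(n_degs = dplyr::coalesce(.data$n_degs, 0L))
    list(deg_tables = deg_tables, trends = trends, deg_counts = deg_counts)
  })
  universes <- lapply(res$deg_tables, function(d) d$gene)

  cosine <- if (length(tissues) >= 2L &&
                dplyr::n_distinct(res$trends$tissue) >= 2L) {
    stage("cosine", tissue_cosine_matrix(res$trends))
  } else NULL
  ectts <- stage("ectts",
                 select_ectts(res$deg_counts, k = config$k_ectts))

  # --- enrichment ----------------------------------------------------------
  enrichment <- NULL; shared <- character(0)
  if (!is.null(study$genesets)) {
    enrichment <- stage("enrich",
      run_enrichment(res$trends, study$genesets, universes,
                     q_max = config$q_max))
    shared <- shared_terms(enrichment, min_tissues = config$min_tissues)
  }

  # --- network hubness -----------------------------------------------------
  centralities <- NULL; hubness <- NULL
  if (!is.null(study$network)) {
    centralities <- stage("netcent", compute_centralities(study$network))
    hubness <- stage("hubness", dplyr::bind_rows(lapply(tissues, function(t) {
      ids <- res$trends$gene[res$trends$tissue == t]
      if (length(ids) == 0L) return(NULL)
      rep <- suppressMessages(hubness_report(centralities, ids))
      if (nrow(rep) > 0) rep$tissue <- t
      rep
    })))
  }

  # --- TF activity ---------------------------------------------------------
  tf_activity <- NULL; key_tfs <- NULL; expr_activity <- NULL
  if (!is.null(study$regulons)) {
    tf_activity <- stage("tfact", dplyr::bind_rows(lapply(tissues, function(t) {
      tr <- dplyr::filter(res$trends, .data$tissue == t)
      if (nrow(tr) == 0L) return(NULL)
      infer_tf_activity(study$regulons, tr, universes[[t]], tissue = t,
                        B = config$B,
                        seed = derive_seed(config$seed, paste0("tf:", t)),
                        q_max = config$q_max)
    })))
    key_tfs <- key_tf_selection(tf_activity, ectts,
                                min_share = config$min_share)
    expr_activity <- suppressMessages(
      expression_activity_correlation(tf_activity, res$deg_tables))
  }

  # --- TAS comparison ------------------------------------------------------
  hits <- NULL; ptsp <- NULL; labels <- NULL
  if (!is.null(study$libraries)) {
    hits <- stage("tascomp", dplyr::bind_rows(lapply(tissues, function(t) {
      lib <- study$libraries[[t]]
      if (is.null(lib)) return(NULL)
      lib <- prune_redundant(lib, scc_cut = config$redundancy_cut,
                             min_overlap = config$min_overlap)
      query <- study$queries[[t]] %g%
        build_tas(study$profiles[[t]]$estrus, study$profiles[[t]]$diestrus)
      suppressMessages(
        match_library(query, lib, scc_threshold = config$scc_threshold,
                      min_overlap = config$min_overlap))
    })))
    ptsp <- ptsp_aggregate(hits,
                           include_reproductive = config$include_reproductive)
    labels <- dplyr::bind_rows(lapply(tissues, function(t) {
      lib <- study$libraries[[t]]
      if (is.null(lib)) return(NULL)
      h <- dplyr::filter(hits, .data$tissue == t)
      s <- label_hierarchy_summary(h, lib)
      if (nrow(s) > 0) s$tissue <- t
      s
    }))
  }

  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    tissues = tissues,
    n_genes = length(unique(unlist(universes)))
  )

  structure(list(
    deg_tables = res$deg_tables, trends = res$trends,
    deg_counts = res$deg_counts, cosine = cosine, ectts = ectts,
    enrichment = enrichment, shared = shared,
    centralities = centralities, hubness = hubness,
    tf_activity = tf_activity, key_tfs = key_tfs,
    expr_activity = expr_activity,
    hits = hits, ptsp = ptsp, labels = labels,
    manifest = manifest
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  tissues: %s\n", paste(x$manifest$tissues, collapse = ", ")))
  cat(sprintf("  DEGs: %s\n",
              paste(sprintf("%s=%d", x$deg_counts$tissue,
                            x$deg_counts$n_degs), collapse = " ")))
  cat(sprintf("  ECTTs: %s\n", paste(x$ectts, collapse = ", ")))
  if (!is.null(x$ptsp)) {
    cat(sprintf("  PTSP: %s\n",
                paste(sprintf("%s:%s", x$ptsp$tissue, x$ptsp$verdict),
                      collapse = " ")))
  }
  invisible(x)
}

#' Write the tabular outputs of a pipeline run
#'
#' DEG tables, cosine matrix, enrichment, hubness, TF activity, hits and
#' PTSP calls as TSVs plus a JSON manifest, all under `dir`.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (t in names(result$deg_tables)) {
    readr::write_tsv(result$deg_tables[[t]],
                     file.path(dir, sprintf("deg_%s.tsv", t)))
  }
  if (!is.null(result$cosine)) {
    cm <- as_tibble(unclass(result$cosine), rownames = "tissue")
    readr::write_tsv(cm, file.path(dir, "cosine.tsv"))
  }
  tabs <- list(enrichment = result$enrichment, hubness = result$hubness,
               tf_activity = result$tf_activity, hits = result$hits,
               ptsp = result$ptsp)
  for (nm in names(tabs)) {
    if (!is.null(tabs[[nm]])) {
      tab <- tabs[[nm]]
      tab <- tab[, !vapply(tab, is.list, logical(1)), drop = FALSE]
      readr::write_tsv(tab, file.path(dir, paste0(nm, ".tsv")))
    }
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the bundled synthetic demonstration
#'
#' Simulates a complete multi-tissue study with planted ground truth, runs
#' the full pipeline on it, and scores the recovery of the planted truth:
#' DEG sensitivity and false discovery proportion, TAS-match sensitivity,
#' TF precision/recall, hub detection, and protective-phase recovery.
#'
#' @param seed Master seed for both the generator and the pipeline.
#' @param config Optional [sim_config()] override (its seed is replaced by
#'   `seed`).
#' @param pconfig Optional [pipeline_config()] override (seed replaced).
#' @param dir Optional output directory for [write_pipeline_outputs()].
#' @return A list: `study`, `result`, `recovery` (named list of recovery
#'   metrics).
#' @export
run_demo <- function(seed = 1L, config = NULL, pconfig = NULL, dir = NULL) {
  cfg <- config %g% sim_config(n_genes = 1500L, n_tissues = 8L,
                               tas_library_size = 40L,
                               net_nodes = 1500L, net_edges = 4500L)
  cfg$seed <- as.integer(seed); class(cfg) <- "sim_config"
  pcfg <- pconfig %g% pipeline_config(k_ectts = min(6L, cfg$n_tissues),
                                      B = 200L)
  pcfg$seed <- as.integer(seed); class(pcfg) <- "pipeline_config"

  study <- simulate_study(cfg)
  result <- run_pipeline(study, pcfg)
  recovery <- score_recovery(study, result, pcfg)
  if (!is.null(dir)) write_pipeline_outputs(result, dir)
  list(study = study, result = result, recovery = recovery)
}

#' Score planted-truth recovery of a pipeline run
#'
#' @param study,result,pconfig Study bundle, pipeline result, pipeline
#'   config.
#' @param min_base_mean Planted genes below this baseline mean are excluded
#'   from the sensitivity denominator: detection power is only defined for
#'   adequately expressed genes.
#' @return Named list of recovery metrics.
#' @keywords internal
#' @export
score_recovery <- function(study, result, pconfig = pipeline_config(),
                           min_base_mean = 50) {
  truth <- study$truth
  # DEG recovery, pooled over tissues
  sens <- purrr::map_dbl(names(truth$deg), function(t) {
    planted <- truth$deg[[t]]$gene[truth$deg[[t]]$base_mean >= min_base_mean]
    called <- result$trends$gene[result$trends$tissue == t]
    if (length(planted) == 0L) return(NA_real_)
    mean(planted %in% called)
  })
  fdp <- purrr::map_dbl(names(truth$deg), function(t) {
    planted <- truth$deg[[t]]$gene
    called <- result$trends$gene[result$trends$tissue == t]
    if (length(called) == 0L) return(NA_real_)
    mean(!called %in% planted)
  })

  # TAS: planted correlated members flagged as hits
  tas_sens <- purrr::map_dbl(names(truth$tas), function(t) {
    planted <- truth$tas[[t]]$id
    h <- result$hits[result$hits$tissue == t, ]
    if (length(planted) == 0L) return(NA_real_)
    mean(planted %in% h$library_id[h$significant])
  })

  # protective phase recovered (non-reproductive tissues with a verdict)
  phase_ok <- NA_real_
  if (!is.null(result$ptsp) && nrow(result$ptsp) > 0) {
    cmp <- result$ptsp |>
      dplyr::mutate(planted = unname(truth$protective_phase[.data$tissue])) |>
      dplyr::filter(.data$verdict != "indeterminate")
    if (nrow(cmp) > 0) {
      phase_ok <- mean((cmp$verdict == "estrus-protective") ==
                        (cmp$planted == "estrus"))
    }
  }

  # TF recovery in the tissue whose trend seeded the regulons
  tf_prec <- tf_rec <- NA_real_
  if (!is.null(result$tf_activity)) {
    t1 <- truth$tf_tissue
    found <- result$tf_activity |>
      dplyr::filter(.data$tissue == t1, .data$significant)
    planted <- truth$tfs
    if (nrow(planted) > 0) {
      hit <- dplyr::inner_join(found, planted, by = "tf") |>
        dplyr::filter(.data$direction.x == .data$direction.y)
      tf_prec <- if (nrow(found) > 0) nrow(hit) / nrow(found) else NA_real_
      tf_rec <- nrow(hit) / nrow(planted)
    }
  }

  # hub signal: degree-greater p for the hub-planted tissue
  hub_p <- NA_real_
  if (!is.null(result$hubness) && nrow(result$hubness) > 0) {
    h <- result$hubness |>
      dplyr::filter(.data$tissue == truth$tf_tissue,
                    .data$index == "degree", .data$alternative == "greater")
    if (nrow(h) == 1L) hub_p <- h$p
  }

  list(
    deg_sensitivity = mean(sens, na.rm = TRUE),
    deg_fdp = mean(fdp, na.rm = TRUE),
    tas_match_sensitivity = mean(tas_sens, na.rm = TRUE),
    protective_phase_recovery = phase_ok,
    tf_precision = tf_prec,
    tf_recall = tf_rec,
    hub_degree_p = hub_p
  )
}
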