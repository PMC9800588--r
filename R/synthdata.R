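#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators into a validated
#' config object. The defaults describe the study design the generators
#' emulate: two estrous-cycle phases (estrus vs diestrus) with three
#' biological replicates per tissue-phase group, a scaled-down transcriptome,
#' and planted ground truth (differential genes, correlated signatures,
#' directionally active transcription factors, network hubs) so every
#' downstream stage can be benchmarked against known answers.
#'
#' @param seed Integer master seed; every generator is a pure function of
#'   (config, seed).
#' @param n_genes Number of genes in the measured universe.
#' @param n_replicates Biological replicates per tissue-phase group.
#' @param lib_size_mean Expected total counts per replicate library.
#' @param nb_dispersion Negative-binomial dispersion phi, with
#'   variance = mu + phi * mu^2; 0 gives Poisson counts.
#' @param deg_fraction Fraction of genes planted as differential.
#' @param deg_log2fc Planted absolute log2 fold change of differential genes.
#' @param n_tissues Number of tissues simulated by [simulate_study()].
#' @param tas_library_size Number of members in a simulated TAS library.
#' @param tas_rho Planted population Spearman correlation (absolute value)
#'   for correlated library members; must lie in (-1, 1).
#' @param tas_correlated_fraction Fraction of library members planted as
#'   correlated with the query (the rest are null).
#' @param label_balance Fraction of library members labeled "beneficial".
#' @param n_tfs,targets_per_tf,tf_consistency Regulon generator: number of
#'   transcription factors, signed targets per TF, and the fraction of a
#'   planted-active TF's measured targets whose trend agrees with
#'   (TF direction x edge sign).
#' @param n_active_tfs Number of TFs planted as directionally active.
#' @param net_nodes,net_edges Directed signaling-network size (nodes grown by
#'   preferential attachment; approximate edge count).
#' @param n_hubs Number of planted high-centrality differential genes; 0
#'   disables hub planting.
#' @param protective_phase Phase planted as tissue-protective ("estrus" or
#'   "diestrus"); couples library outcome labels to correlation signs.
#'
#' @return A `sim_config` object (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 500)
#' cfg$n_replicates
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 2000L,
                       n_replicates = 3L,
                       lib_size_mean = 1e6,
                       nb_dispersion = 0.1,
                       deg_fraction = 0.1,
                       deg_log2fc = 2,
                       n_tissues = 15L,
                       tas_library_size = 80L,
                       tas_rho = 0.3,
                       tas_correlated_fraction = 0.5,
                       label_balance = 0.5,
                       n_tfs = 30L,
                       targets_per_tf = 20L,
                       tf_consistency = 0.9,
                       n_active_tfs = 6L,
                       net_nodes = n_genes,
                       net_edges = 3L * n_genes,
                       n_hubs = 20L,
                       protective_phase = c("estrus", "diestrus")) {
  protective_phase <- match.arg(protective_phase)
  seed <- assert_count(seed, "seed", min = 0L)
  n_genes <- assert_count(n_genes, "n_genes", min = 10L)
  n_replicates <- assert_count(n_replicates, "n_replicates", min = 1L)
  if (!is.numeric(lib_size_mean) || length(lib_size_mean) != 1L ||
      is.na(lib_size_mean) || lib_size_mean <= 0) {
    abort("`lib_size_mean` must be a single positive number.",
          class = "estrocycle_invalid_config")
  }
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0) {
    abort("`nb_dispersion` must be >= 0.",
          class = "estrocycle_invalid_config")
  }
  assert_prob(deg_fraction, "deg_fraction")
  assert_prob(tas_correlated_fraction, "tas_correlated_fraction")
  assert_prob(label_balance, "label_balance")
  assert_prob(tf_consistency, "tf_consistency")
  if (!is.numeric(tas_rho) || abs(tas_rho) >= 1) {
    abort("`tas_rho` must lie in (-1, 1).",
          class = "estrocycle_invalid_config")
  }
  n_tissues <- assert_count(n_tissues, "n_tissues", min = 1L)
  tas_library_size <- assert_count(tas_library_size, "tas_library_size", 1L)
  n_tfs <- assert_count(n_tfs, "n_tfs", 1L)
  targets_per_tf <- assert_count(targets_per_tf, "targets_per_tf", 3L)
  n_active_tfs <- assert_count(n_active_tfs, "n_active_tfs", 0L)
  net_nodes <- assert_count(net_nodes, "net_nodes", 10L)
  net_edges <- assert_count(net_edges, "net_edges", 1L)
  if (net_edges < net_nodes - 1L) {
    abort("`net_edges` must be at least `net_nodes` - 1.",
          class = "estrocycle_invalid_config")
  }
  n_hubs <- assert_count(n_hubs, "n_hubs", 0L)

  structure(list(
    seed = seed, n_genes = n_genes, n_replicates = n_replicates,
    lib_size_mean = lib_size_mean, nb_dispersion = nb_dispersion,
    deg_fraction = deg_fraction, deg_log2fc = deg_log2fc,
    n_tissues = n_tissues, tas_library_size = tas_library_size,
    tas_rho = tas_rho, tas_correlated_fraction = tas_correlated_fraction,
    label_balance = label_balance, n_tfs = n_tfs,
    targets_per_tf = targets_per_tf, tf_consistency = tf_consistency,
    n_active_tfs = n_active_tfs, net_nodes = net_nodes,
    net_edges = net_edges, n_hubs = n_hubs,
    protective_phase = protective_phase
  ), class = "sim_config")
}

sim_gene_ids <- function(n) sprintf("g%05d", seq_len(n))

#' Construct an expression profile
#'
#' One tissue-phase group: a gene-by-replicate count matrix plus per-replicate
#' library sizes (column sums).
#'
#' @param counts Non-negative integer matrix, rows named by gene id.
#' @param tissue,phase Group identifiers; `phase` is "estrus" or "diestrus".
#' @return An `expression_profile` object.
#' @export
expression_profile <- function(counts, tissue, phase) {
  if (is.null(rownames(counts))) {
    abort("`counts` must have gene ids as rownames.")
  }
  if (anyDuplicated(rownames(counts))) {
    abort("gene ids must be unique.")
  }
  if (any(counts < 0)) abort("counts must be non-negative.")
  colnames(counts) <- sprintf("%s_%s_rep%d", tissue, phase,
                              seq_len(ncol(counts)))
  structure(list(tissue = tissue, phase = phase, counts = counts,
                 lib_sizes = colSums(counts)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s / %s: %d genes x %d replicates\n",
              x$tissue, x$phase, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Simulate phase-contrasted RNA-seq counts with planted differential genes
#'
#' Draws negative-binomial counts for one tissue in both cycle phases.
#' Per-gene baseline rates are log-normal and rescaled so expected library
#' totals match `lib_size_mean`; a `deg_fraction` of genes has its estrus
#' rate multiplied by `2^(+/- deg_log2fc)` (half up, half down in estrus).
#'
#' @param config A [sim_config()].
#' @param tissue Tissue identifier attached to the profiles.
#' @param deg_plan Optional tibble (`gene`, `sign`) fixing which genes are
#'   differential and in which direction (used by [simulate_study()] to
#'   share a DEG core across tissues); by default a random
#'   `deg_fraction` of genes is planted, alternating up/down.
#' @return A list with elements `estrus` and `diestrus`
#'   ([expression_profile()]s over the same ordered gene ids) and `truth`,
#'   a tibble of planted differential genes (`gene`, `sign`, `log2fc`,
#'   `base_mean`).
#' @examples
#' sim <- simulate_counts(sim_config(seed = 1, n_genes = 200))
#' sim$truth
#' @export
simulate_counts <- function(config, tissue = "tissue1", deg_plan = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_stage_seed(config$seed, paste0("counts:", tissue), {
    n <- config$n_genes
    genes <- sim_gene_ids(n)
    w <- rlnorm(n, meanlog = 0, sdlog = 1.5)
    mu_base <- w / sum(w) * config$lib_size_mean

    if (!is.null(deg_plan)) {
      if (!all(deg_plan$gene %in% genes)) {
        abort("`deg_plan` refers to genes outside the simulated universe.")
      }
      deg_idx <- match(deg_plan$gene, genes)
      signs <- deg_plan$sign
    } else {
      n_deg <- round(config$deg_fraction * n)
      deg_idx <- if (n_deg > 0) sample.int(n, n_deg) else integer(0)
      signs <- rep_len(c(1, -1), n_deg)
    }
    mu_estrus <- mu_base
    mu_estrus[deg_idx] <- mu_base[deg_idx] * 2^(signs * config$deg_log2fc)

    draw <- function(mu) {
      m <- vapply(seq_len(config$n_replicates), function(r) {
        if (config$nb_dispersion == 0) rpois(n, mu)
        else rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
      }, numeric(n))
      m <- matrix(m, nrow = n)
      rownames(m) <- genes
      m
    }
    est <- expression_profile(draw(mu_estrus), tissue, "estrus")
    die <- expression_profile(draw(mu_base), tissue, "diestrus")
    truth <- tibble(gene = genes[deg_idx], sign = signs,
                    log2fc = signs * config$deg_log2fc,
                    base_mean = mu_base[deg_idx])
    list(estrus = est, diestrus = die, truth = truth)
  })
}

tas_label_paths <- list(
  beneficial = list(c("beneficial", "chemical treatment"),
                    c("beneficial", "lifestyle"),
                    c("beneficial", "disease", "recovery")),
  deleterious = list(c("deleterious", "disease", "cancer"),
                     c("deleterious", "disease", "inflammation"),
                     c("deleterious", "chemical treatment"))
)

#' Simulate a labeled TAS library with planted correlations
#'
#' Builds `tas_library_size` signatures over the query's gene space. A
#' planted fraction is rank-correlated with the query through a Gaussian
#' copula: the query values are mapped to normal scores `z`, and a member
#' with target Spearman correlation `rho` is `r z + sqrt(1 - r^2) eps` with
#' `r = 2 sin(pi rho / 6)` (the exact bivariate-normal relation between
#' Pearson and Spearman correlation). Correlation signs are coupled to
#' outcome labels: when the planted protective phase matches the query's
#' phase, beneficial members correlate positively and deleterious members
#' negatively (and conversely otherwise).
#'
#' @param config A [sim_config()].
#' @param query A [tas()] (typically the estrus-induced signature of one
#'   tissue) with at least 100 genes.
#' @param protective_phase Override of `config$protective_phase`, useful when
#'   different tissues are planted with different protective phases.
#' @return A list with `library` (a [tas_library()]) and `truth`, a tibble
#'   (`id`, `rho`, `outcome`) of the planted correlated members.
#' @export
simulate_tas_library <- function(config, query,
                                 protective_phase = config$protective_phase) {
  stopifnot(inherits(config, "sim_config"))
  query <- as_tas(query)
  n <- nrow(query)
  if (n < 100L) abort("`query` must have at least 100 genes.")
  if (abs(config$tas_rho) >= 1) {
    abort("`tas_rho` must lie in (-1, 1).", class = "estrocycle_invalid_config")
  }
  qphase <- attr(query, "phase") %g% "estrus"
  with_stage_seed(config$seed, paste0("taslib:", tas_id(query)), {
    size <- config$tas_library_size
    n_cor <- round(config$tas_correlated_fraction * size)
    ids <- sprintf("%s_tas%03d", tas_tissue(query), seq_len(size))
    outcome <- ifelse(runif(size) < config$label_balance,
                      "beneficial", "deleterious")
    # outcome label -> sign of the planted correlation with the query
    pos_outcome <- if (identical(protective_phase, qphase))
      "beneficial" else "deleterious"
    rho <- numeric(size)
    rho[seq_len(n_cor)] <- ifelse(outcome[seq_len(n_cor)] == pos_outcome,
                                  abs(config$tas_rho), -abs(config$tas_rho))
    z <- qnorm((rank(query$log2fc, ties.method = "average") - 0.5) / n)
    members <- lapply(seq_len(size), function(i) {
      r <- 2 * sin(pi * rho[i] / 6)
      vals <- r * z + sqrt(1 - r^2) * rnorm(n)
      path <- tas_label_paths[[outcome[i]]]
      path <- path[[sample.int(length(path), 1L)]]
      tas(genes = query$gene, values = vals, id = ids[i],
          tissue = tas_tissue(query), outcome = outcome[i],
          label_path = path)
    })
    lib <- tas_library(members)
    truth <- tibble(id = ids[seq_len(n_cor)], rho = rho[seq_len(n_cor)],
                    outcome = outcome[seq_len(n_cor)])
    list(library = lib, truth = truth)
  })
}

#' Simulate a directed signaling network with optional planted hubs
#'
#' Grows a directed preferential-attachment graph whose node set covers the
#' measured genes (gene ids are assigned to graph nodes by random
#' permutation, so without planting the differential genes are exchangeable
#' with background). When `n_hubs > 0`, that many differential genes receive
#' extra randomly oriented edges until their total degree exceeds the 95th
#' percentile of the pre-planting degree distribution.
#'
#' @param config A [sim_config()].
#' @param genes Character vector of measured gene ids.
#' @param deg_ids Differential gene ids from which hubs are planted.
#' @return A list with `network` (an igraph directed graph) and `truth`, a
#'   tibble of planted hub ids.
#' @export
simulate_network <- function(config, genes, deg_ids = character(0)) {
  stopifnot(inherits(config, "sim_config"))
  if (config$net_nodes < 10L) {
    abort("`net_nodes` must be >= 10.", class = "estrocycle_invalid_config")
  }
  if (config$net_edges < config$net_nodes - 1L) {
    abort("`net_edges` must be at least `net_nodes` - 1.",
          class = "estrocycle_invalid_config")
  }
  n_nodes <- max(config$net_nodes, length(genes))
  with_stage_seed(config$seed, "network", {
    m <- max(1L, round(config$net_edges / n_nodes))
    g <- igraph::sample_pa(n_nodes, m = m, directed = TRUE)
    labels <- c(genes, if (n_nodes > length(genes))
      sprintf("x%05d", seq_len(n_nodes - length(genes))))
    igraph::V(g)$name <- sample(labels)

    hubs <- character(0)
    n_hubs <- min(config$n_hubs, length(deg_ids))
    if (n_hubs > 0) {
      hubs <- sample(deg_ids, n_hubs)
      deg <- igraph::degree(g, mode = "all")
      # hubs sit decisively in the degree tail, not at its edge
      target <- 2 * ceiling(stats::quantile(deg, 0.95))
      for (h in hubs) {
        need <- target - deg[[h]]
        if (need <= 0) next
        partners <- sample(setdiff(igraph::V(g)$name, h), need)
        flip <- runif(need) < 0.5
        el <- rbind(cbind(h, partners)[flip, , drop = FALSE],
                    cbind(partners, h)[!flip, , drop = FALSE])
        g <- igraph::add_edges(g, t(el))
      }
    }
    list(network = g, truth = tibble(hub = hubs))
  })
}

#' Simulate signed regulons with planted directionally active TFs
#'
#' Each transcription factor receives `targets_per_tf` signed targets. For
#' the `n_active_tfs` planted-active TFs (random direction +/-1), targets are
#' drawn from the differential genes so that a fraction `tf_consistency` has
#' edge sign equal to `trend * direction` (consistent) and the remainder the
#' opposite sign. Inactive TFs draw targets from the whole measured universe
#' with random signs, so their consistency follows the global trend
#' distribution.
#'
#' @param config A [sim_config()].
#' @param trend A trend vector (tibble `gene`, `trend` or named +/-1 vector)
#'   over the differential genes.
#' @param genes Character vector of all measured gene ids.
#' @param tfs_are_genes When TRUE, transcription factors are themselves
#'   measured genes: each planted-active TF's id is drawn from the
#'   differential genes whose own trend equals the TF's planted direction,
#'   emulating the coupling between a TF's expression change and its
#'   regulatory activity; inactive TFs are random non-differential genes.
#'   When FALSE (default) TFs get synthetic ids `TF01`, `TF02`, ...
#' @return A list with `regulons` (tibble `tf`, `target`, `sign`) and
#'   `truth`, a tibble (`tf`, `direction`) of planted active TFs.
#' @export
simulate_regulons <- function(config, trend, genes, tfs_are_genes = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$targets_per_tf < 3L) {
    abort("`targets_per_tf` must be >= 3.",
          class = "estrocycle_invalid_config")
  }
  assert_prob(config$tf_consistency, "tf_consistency")
  tr <- as_trend_map(trend)
  deg_ids <- names(tr)
  with_stage_seed(config$seed, "regulons", {
    n_active <- min(config$n_active_tfs, config$n_tfs)
    dirs <- sample(c(1, -1), n_active, replace = TRUE)
    k <- config$targets_per_tf

    if (tfs_are_genes) {
      # active TFs: differential genes whose own trend matches their
      # planted direction (expression tracks activity); inactive TFs:
      # non-differential genes
      tfs <- character(config$n_tfs)
      used <- character(0)
      for (i in seq_len(n_active)) {
        cand <- setdiff(names(tr)[tr == dirs[i]], used)
        if (length(cand) == 0L) cand <- setdiff(deg_ids, used)
        tfs[i] <- sample(cand, 1L)
        used <- c(used, tfs[i])
      }
      rest <- setdiff(genes, c(deg_ids, used))
      tfs[seq_len(config$n_tfs) > n_active] <-
        sample(rest, config$n_tfs - n_active)
    } else {
      tfs <- sprintf("TF%02d", seq_len(config$n_tfs))
    }

    # planting needs at least 3 differential targets; with a small DEG set
    # the planted regulon shrinks to the available DEGs
    k_eff <- min(k, length(deg_ids))
    plantable <- if (k_eff >= 3L) seq_len(n_active) else integer(0)
    rows <- lapply(seq_along(tfs), function(i) {
      tf <- tfs[i]
      if (i %in% plantable) {
        targets <- sample(setdiff(deg_ids, tf), min(k_eff,
                                                    length(deg_ids) - 1L))
        n_cons <- round(config$tf_consistency * length(targets))
        sign <- ifelse(seq_along(targets) <= n_cons,
                       tr[targets] * dirs[i], -tr[targets] * dirs[i])
      } else {
        targets <- sample(setdiff(genes, tf), min(k, length(genes) - 1L))
        sign <- sample(c(1, -1), length(targets), replace = TRUE)
      }
      tibble(tf = tf, target = targets, sign = as.numeric(sign))
    })
    truth <- tibble(tf = tfs[plantable],
                    direction = ifelse(dirs[plantable] > 0, "up", "down"))
    list(regulons = dplyr::bind_rows(rows), truth = truth)
  })
}

#' Simulate a full multi-tissue study
#'
#' Generates, for `n_tissues` tissues, phase-contrasted count profiles with
#' planted differential genes built from a shared core plus tissue-specific
#' extras: all tissues regulate the core genes, with two tissue modules of
#' opposite core orientation (so trend-based tissue clustering has the
#' two-block structure seen in multi-tissue designs) and a tissue-varying
#' extra burden (so tissue prioritization has signal). Also generates a
#' per-tissue TAS library planted with an alternating protective phase, a
#' shared signaling network with hubs planted from the first tissue's
#' differential genes, and a shared regulon set planted against the core
#' trend with gene-identified TFs (so a planted TF is recoverable in every
#' tissue, with module-dependent direction, and its own expression change
#' tracks its activity).
#'
#' @param config A [sim_config()].
#' @param tissues Optional tissue names (defaults to the 15 mouse tissues of
#'   the emulated design, truncated to `n_tissues`).
#' @param core_fraction Fraction of each tissue's planted DEG budget drawn
#'   from the shared core.
#' @return A list: `profiles` (per tissue: estrus/diestrus profiles),
#'   `genesets`, `network`, `regulons`, `libraries`, `queries`, and `truth`
#'   (per-tissue planted DEGs, library truths, protective phases, tissue
#'   modules, hub and TF truths).
#' @export
simulate_study <- function(config, tissues = NULL, core_fraction = 0.6) {
  stopifnot(inherits(config, "sim_config"))
  default_tissues <- c("aorta", "vein", "BAT", "WAT", "heart", "kidney",
                       "liver", "muscle", "stomach", "duodenum", "cerebrum",
                       "hypothalamus", "ovary", "uterus", "spleen")
  tissues <- tissues %g% rep_len(default_tissues, config$n_tissues)
  tissues <- tissues[seq_len(min(length(tissues), config$n_tissues))]
  genes <- sim_gene_ids(config$n_genes)

  burden <- with_stage_seed(config$seed, "burden",
                            runif(length(tissues), 0.3, 1.7))
  protective <- rep_len(c("estrus", "diestrus"), length(tissues))
  names(protective) <- tissues
  # two tissue modules with opposite orientation of the shared DEG core
  module <- rep_len(c(1, -1), length(tissues))
  names(module) <- tissues

  n_deg_base <- round(config$deg_fraction * config$n_genes)
  n_core <- round(core_fraction * n_deg_base)
  core <- with_stage_seed(config$seed, "core", {
    tibble(gene = sample(genes, n_core),
           sign = rep_len(c(1, -1), n_core))
  })

  profiles <- list(); deg_truth <- list()
  libraries <- list(); lib_truth <- list(); queries <- list()
  for (i in seq_along(tissues)) {
    plan <- with_stage_seed(config$seed, paste0("plan:", tissues[i]), {
      n_extra <- max(0L, round(burden[i] * n_deg_base) - n_core)
      extra_pool <- setdiff(genes, core$gene)
      extras <- sample(extra_pool, min(n_extra, length(extra_pool)))
      dplyr::bind_rows(
        tibble(gene = core$gene, sign = core$sign * module[[i]]),
        tibble(gene = extras, sign = rep_len(c(1, -1), length(extras))))
    })
    sim <- simulate_counts(config, tissue = tissues[i], deg_plan = plan)
    profiles[[tissues[i]]] <- sim[c("estrus", "diestrus")]
    deg_truth[[tissues[i]]] <- sim$truth
    q <- build_tas(sim$estrus, sim$diestrus, id = paste0(tissues[i], "_query"))
    queries[[tissues[i]]] <- q
    lib <- simulate_tas_library(config, q,
                                protective_phase = protective[[i]])
    libraries[[tissues[i]]] <- lib$library
    lib_truth[[tissues[i]]] <- lib$truth
  }

  net <- simulate_network(config, genes, deg_truth[[1]]$gene)
  core_trend <- tibble(gene = core$gene, trend = core$sign * module[[1]])
  reg <- simulate_regulons(config, core_trend, genes, tfs_are_genes = TRUE)

  # gene sets: one term planted from each tissue's DEGs (so a term built
  # from genes differential in many tissues exercises the shared-term rule)
  # plus random background sets
  genesets <- with_stage_seed(config$seed, "genesets", {
    shared_members <- unique(unlist(lapply(deg_truth, function(d)
      head(d$gene, 15L))))
    planted1 <- if (nrow(deg_truth[[1]]) > 0)
      sample(deg_truth[[1]]$gene, min(30L, nrow(deg_truth[[1]]))) else
        character(0)
    rand <- lapply(seq_len(15L), function(i) sample(genes, 40L))
    tibble(
      id = c("SET_SHARED", "SET_PLANTED1", sprintf("SET_RAND%02d", 1:15)),
      name = c("planted shared term", "planted tissue-1 term",
               sprintf("random set %02d", 1:15)),
      collection = "custom",
      members = c(list(shared_members), list(planted1), rand)
    )
  })

  list(
    profiles = profiles,
    genesets = genesets,
    queries = queries,
    libraries = libraries,
    network = net$network,
    regulons = reg$regulons,
    truth = list(deg = deg_truth, tas = lib_truth,
                 protective_phase = protective,
                 module = module, core = core,
                 hubs = net$truth, tfs = reg$truth,
                 tf_tissue = tissues[1])
  )
}
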