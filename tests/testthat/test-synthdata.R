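test_that("sim_config validates fractions, dispersion and network size", {
  expect_s3_class(sim_config(seed = 1), "sim_config")
  expect_error(sim_config(deg_fraction = 1.2),
               class = "estrocycle_invalid_config")
  expect_error(sim_config(nb_dispersion = -0.1),
               class = "estrocycle_invalid_config")
  expect_error(sim_config(lib_size_mean = 0),
               class = "estrocycle_invalid_config")
  expect_error(sim_config(tas_rho = 1),
               class = "estrocycle_invalid_config")
  expect_error(sim_config(net_nodes = 100, net_edges = 50),
               class = "estrocycle_invalid_config")
})

test_that("count generator is deterministic and shares ordered gene ids", {
  cfg <- sim_config(seed = 7, n_genes = 300)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$estrus$counts, b$estrus$counts)
  expect_identical(a$diestrus$counts, b$diestrus$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(rownames(a$estrus$counts), rownames(a$diestrus$counts))
  expect_true(all(a$truth$gene %in% rownames(a$estrus$counts)))
  expect_identical(unname(a$estrus$lib_sizes), unname(colSums(a$estrus$counts)))
})

test_that("deg_fraction = 0 gives an exchangeable null and dispersion = 0 is Poisson", {
  cfg <- sim_config(seed = 3, n_genes = 4000, deg_fraction = 0,
                    nb_dispersion = 0, n_replicates = 30)
  sim <- simulate_counts(cfg)
  expect_equal(nrow(sim$truth), 0)
  # Poisson: per-gene replicate variance ~ mean; index of dispersion near 1
  m <- rowMeans(sim$estrus$counts)
  v <- apply(sim$estrus$counts, 1, var)
  keep <- m >= 20
  expect_gt(sum(keep), 500)
  expect_equal(mean(v[keep] / m[keep]), 1, tolerance = 0.05)
  # same NB parameters in both phases: pooled rates comparable
  zt <- deg_ztest(rowSums(sim$estrus$counts), sum(sim$estrus$lib_sizes),
                  rowSums(sim$diestrus$counts), sum(sim$diestrus$lib_sizes))
  expect_lt(mean(zt$p <= 0.05), 0.08)
})

test_that("planted DEGs carry the configured fold change in the estrus rates", {
  cfg <- sim_config(seed = 11, n_genes = 1000, deg_log2fc = 3,
                    n_replicates = 20, nb_dispersion = 0)
  sim <- simulate_counts(cfg)
  up <- sim$truth$gene[sim$truth$sign > 0 & sim$truth$base_mean > 100]
  obs <- log2(rowSums(sim$estrus$counts[up, , drop = FALSE]) /
                rowSums(sim$diestrus$counts[up, , drop = FALSE]))
  expect_equal(mean(obs), 3, tolerance = 0.15)
})

test_that("TAS library planting hits its Spearman targets and is reproducible", {
  withr::local_seed(101)
  cfg <- sim_config(seed = 5, n_genes = 200, tas_library_size = 30,
                    tas_rho = 0, tas_correlated_fraction = 0)
  q <- tas(sprintf("g%05d", 1:500), rnorm(500), id = "q", tissue = "aorta")
  lib <- simulate_tas_library(cfg, q)
  # null members: sample SCC within the null band sd ~ 1/sqrt(n-1)
  sccs <- vapply(lib$library$members, function(m)
    spearman_scc(q$log2fc, m$log2fc), numeric(1))
  expect_lt(max(abs(sccs)), 5 / sqrt(499))
  expect_equal(sd(sccs), 1 / sqrt(499), tolerance = 0.5)

  lib2 <- simulate_tas_library(cfg, q)
  expect_identical(lib$library$meta, lib2$library$meta)
  expect_identical(lib$library$members[[3]]$log2fc,
                   lib2$library$members[[3]]$log2fc)
})

test_that("strong planted correlation is realized on the rank scale", {
  withr::local_seed(101)
  # population rho 0.99 at n = 10,000: sample SCC within 0.02 (20 seeds)
  devs <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, tas_library_size = 1, tas_rho = 0.99,
                      tas_correlated_fraction = 1, label_balance = 1)
    q <- tas(sprintf("g%05d", 1:10000), rnorm(10000), id = "q", tissue = "a")
    lib <- simulate_tas_library(cfg, q)
    spearman_scc(q$log2fc, lib$library$members[[1]]$log2fc) - 0.99
  }, numeric(1))
  expect_lt(max(abs(devs)), 0.02)
})

test_that("library outcome labels couple to the planted protective phase", {
  withr::local_seed(101)
  cfg <- sim_config(seed = 9, tas_library_size = 40, tas_rho = 0.5,
                    tas_correlated_fraction = 1)
  q <- tas(sprintf("g%05d", 1:400), rnorm(400), id = "q", tissue = "a")
  for (phase in c("estrus", "diestrus")) {
    lib <- simulate_tas_library(cfg, q, protective_phase = phase)
    expected_sign <- ifelse(lib$truth$outcome == "beneficial", 1, -1) *
      (if (phase == "estrus") 1 else -1)
    expect_identical(sign(lib$truth$rho), expected_sign)
    # planted ids resolve in the generated library
    expect_true(all(lib$truth$id %in% lib$library$meta$id))
  }
})

test_that("network generator plants hubs above the degree 95th percentile", {
  withr::local_seed(101)
  cfg <- sim_config(seed = 13, n_genes = 400, net_nodes = 400,
                    net_edges = 1200, n_hubs = 10)
  genes <- sprintf("g%05d", 1:400)
  degs <- sample(genes, 40)
  net <- simulate_network(cfg, genes, degs)
  expect_equal(igraph::vcount(net$network), 400)
  expect_true(all(net$truth$hub %in% degs))
  deg_all <- igraph::degree(net$network, mode = "all")
  expect_true(all(deg_all[net$truth$hub] > quantile(deg_all, 0.95) - 1))

  # planting disabled: DEG and background degrees indistinguishable
  # (rank-sum p uniform over seeds; moderate seed count here)
  ps <- vapply(1:25, function(s) {
    cfg0 <- sim_config(seed = s, n_genes = 400, net_nodes = 400,
                       net_edges = 1200, n_hubs = 0)
    net0 <- simulate_network(cfg0, genes, degs)
    d <- igraph::degree(net0$network, mode = "all")
    hubness_test(d[degs], d[setdiff(genes, degs)], "greater")$p
  }, numeric(1))
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(min(ps), 0.001)
})

test_that("regulon generator enforces planted consistency and null behavior", {
  withr::local_seed(101)
  genes <- sprintf("g%05d", 1:500)
  trend <- tibble::tibble(gene = sample(genes, 100),
                          trend = sample(c(1, -1), 100, replace = TRUE))
  # full consistency: every measured target trend equals dir * sign
  cfg <- sim_config(seed = 2, n_genes = 500, n_tfs = 5, n_active_tfs = 5,
                    targets_per_tf = 10, tf_consistency = 1)
  reg <- simulate_regulons(cfg, trend, genes)
  tr <- setNames(trend$trend, trend$gene)
  for (i in seq_len(nrow(reg$truth))) {
    r <- dplyr::filter(reg$regulons, tf == reg$truth$tf[i])
    dir_sign <- if (reg$truth$direction[i] == "up") 1 else -1
    expect_true(all(tr[r$target] == dir_sign * r$sign))
  }
  # inactive TFs score within the permutation null band
  cfg0 <- sim_config(seed = 4, n_genes = 500, n_tfs = 10, n_active_tfs = 0,
                     targets_per_tf = 10)
  reg0 <- simulate_regulons(cfg0, trend, genes)
  ps <- vapply(unique(reg0$regulons$tf), function(f) {
    r <- dplyr::filter(reg0$regulons, tf == f)
    res <- permutation_null(r, trend, genes, "up", B = 200, seed = 1)
    if (is.null(res)) NA_real_ else res$p
  }, numeric(1))
  expect_gt(min(ps, na.rm = TRUE), 0.005)
  # reproducibility
  expect_identical(simulate_regulons(cfg0, trend, genes)$regulons,
                   reg0$regulons)
})
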