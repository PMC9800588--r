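test_that("consistency score counts concordant minus discordant targets", {
  trend <- c(g1 = 1, g2 = 1, g3 = 1, g4 = -1)
  # 3 activating targets, all up, direction up -> 3
  reg <- tibble::tibble(target = c("g1", "g2", "g3"), sign = c(1, 1, 1))
  expect_equal(consistency_score(reg, trend, "up")$score, 3)
  # 2 consistent + 1 contradicting
  reg2 <- tibble::tibble(target = c("g1", "g2", "g4"), sign = c(1, 1, 1))
  expect_equal(consistency_score(reg2, trend, "up")$score, 1)
  # unknown-direction edges add 1 per DEG target
  reg3 <- tibble::tibble(target = c("g1", "g4", "zz"), sign = c(0, 0, 0))
  cs <- consistency_score(reg3, trend, "down")
  expect_equal(cs$score, 2)
  expect_equal(cs$n_measured, 2)
  # regulon disjoint from the DEGs is not testable
  expect_false(consistency_score(
    tibble::tibble(target = "zz", sign = 1), trend, "up")$testable)
})

test_that("score is antisymmetric in direction for fully signed regulons", {
  withr::local_seed(5)
  trend <- setNames(sample(c(1, -1), 50, replace = TRUE),
                    sprintf("g%02d", 1:50))
  for (i in 1:10) {
    reg <- tibble::tibble(target = sample(names(trend), 12),
                          sign = sample(c(1, -1), 12, replace = TRUE))
    expect_equal(consistency_score(reg, trend, "up")$score,
                 -consistency_score(reg, trend, "down")$score)
  }
})

test_that("permutation null is valid, reproducible and detects planted TFs", {
  withr::local_seed(7)
  genes <- sprintf("g%04d", 1:800)
  trend <- tibble::tibble(gene = sample(genes, 120),
                          trend = sample(c(1, -1), 120, replace = TRUE))
  # planted: 18 of 20 targets consistent with direction "up"
  tr <- setNames(trend$trend, trend$gene)
  targets <- sample(trend$gene, 20)
  sign <- tr[targets]; sign[1:2] <- -sign[1:2]
  reg <- tibble::tibble(target = targets, sign = unname(sign))
  res <- permutation_null(reg, trend, genes, "up", B = 500, seed = 3)
  expect_lte(res$p, 0.01)
  expect_equal(res$n_measured, 20)
  # determinism and p in (0, 1]
  res2 <- permutation_null(reg, trend, genes, "up", B = 500, seed = 3)
  expect_identical(res, res2)
  expect_gt(res$p, 0)
  # not-testable regulon skipped
  expect_null(permutation_null(tibble::tibble(target = "none", sign = 1),
                               trend, c(genes, "none"), "up", B = 100))
  expect_error(permutation_null(reg, trend, genes, "up", B = 10), ">= 100")
})

test_that("null permutation p-values are roughly uniform for inactive TFs", {
  withr::local_seed(19)
  genes <- sprintf("g%04d", 1:500)
  trend <- tibble::tibble(gene = sample(genes, 80),
                          trend = sample(c(1, -1), 80, replace = TRUE))
  ps <- vapply(1:40, function(i) {
    # ensure testability: a few targets inside the trend domain
    targets <- c(sample(trend$gene, 5), sample(setdiff(genes, trend$gene), 10))
    reg <- tibble::tibble(target = targets,
                          sign = sample(c(1, -1), 15, replace = TRUE))
    permutation_null(reg, trend, genes, "up", B = 200, seed = i)$p
  }, numeric(1))
  # discrete grid on k/(B+1); calibration: P(p <= a) <= a approximately
  expect_lte(mean(ps <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
  expect_gt(mean(ps), 0.3)
})

test_that("infer_tf_activity applies one-sided BH, one direction per TF", {
  withr::local_seed(3)
  cfg <- sim_config(seed = 6, n_genes = 800, n_tfs = 15, n_active_tfs = 4,
                    targets_per_tf = 20, tf_consistency = 0.9)
  sim <- simulate_counts(cfg)
  d <- deg_test(sim$estrus, sim$diestrus)
  trend <- tibble::tibble(gene = sim$truth$gene, trend = sim$truth$sign)
  reg <- simulate_regulons(cfg, trend, d$gene)
  act <- infer_tf_activity(reg$regulons, trend, d$gene, tissue = "aorta",
                           B = 300, seed = 9)
  # at most one row per TF (untestable regulons are skipped),
  # activity sign matches direction, cap at 16
  expect_lte(nrow(act), dplyr::n_distinct(reg$regulons$tf))
  expect_equal(anyDuplicated(act$tf), 0)
  expect_true(all(reg$truth$tf %in% act$tf))
  expect_true(all(sign(act$activity_score) ==
                    ifelse(act$direction == "up", 1, -1)))
  expect_true(all(abs(act$activity_score) <= 16))
  expect_true(all(act$significant == (act$q <= 0.05)))
  # planted TFs recovered with their planted directions
  found <- dplyr::filter(act, significant)
  hit <- dplyr::inner_join(found, reg$truth, by = "tf")
  expect_true(all(hit$direction.x == hit$direction.y))
  expect_gte(nrow(hit) / nrow(reg$truth), 0.75)
})

test_that("key-TF selection requires sharing across enough target tissues", {
  res <- tibble::tibble(
    tf = c(rep("TFa", 4), rep("TFb", 3), "TFc"),
    tissue = c(paste0("t", 1:4), paste0("t", 1:3), "t9"),
    direction = "up", significant = TRUE)
  ectts <- paste0("t", 1:6)
  sel <- key_tf_selection(res, ectts, min_share = 4)
  expect_setequal(unique(sel$tf), "TFa")
  expect_equal(nrow(key_tf_selection(res[0, ], ectts)), 0)
})

test_that("expression-activity correlation behaves on monotone and shuffled pairs", {
  withr::local_seed(21)
  # activity a strictly monotone function of the TF's fold change -> SCC 1
  tfs <- sprintf("TF%02d", 1:10)
  lfc <- rnorm(10)
  res <- tibble::tibble(tf = tfs, tissue = "t", direction = "up",
                        activity_score = exp(lfc), significant = TRUE)
  degtab <- list(t = tibble::tibble(gene = tfs, log2fc = lfc))
  ea <- expression_activity_correlation(res, degtab)
  expect_equal(ea$scc, 1)
  expect_equal(ea$n_pairs, 10)
  # shuffled pairing: SCC within the null band
  sccs <- vapply(1:30, function(i) {
    res$activity_score <- sample(res$activity_score)
    expression_activity_correlation(res, degtab)$scc
  }, numeric(1))
  expect_lt(abs(mean(sccs)), 0.25)
  # fewer than 3 pairs is not computable
  ea0 <- expression_activity_correlation(res[1:2, ], degtab)
  expect_true(is.na(ea0$scc))
})
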