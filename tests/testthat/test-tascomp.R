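test_that("TAS construction drops both-zero genes and uses pooled rates", {
  counts_a <- rbind(g1 = c(10, 30), g2 = c(0, 0), g3 = c(7, 3))
  counts_b <- rbind(g1 = c(5, 5), g2 = c(0, 0), g3 = c(20, 20))
  pa <- make_profile(counts_a); pb <- make_profile(counts_b, phase = "diestrus")
  q <- build_tas(pa, pb)
  expect_s3_class(q, "tas")
  expect_identical(q$gene, c("g1", "g3"))   # g2 zero in both -> dropped
  expect_equal(q$log2fc,
               pooled_log2fc(c(40, 10), sum(counts_a), c(10, 40), sum(counts_b)))
  # identical profiles give the all-zero signature
  q0 <- build_tas(pa, make_profile(counts_a, phase = "diestrus"))
  expect_true(all(q0$log2fc == 0))
  expect_error(tas(c("a", "b"), c(1, Inf), id = "x"), "finite")
})

test_that("spearman_scc matches the independent rank oracle, ties included", {
  expect_equal(spearman_scc(1:10, 1:10), 1)
  expect_equal(spearman_scc(1:10, exp(-(1:10))), -1)   # decreasing transform
  expect_equal(spearman_scc(c(1, 2, 3, 3), c(2, 1, 4, 4)), 7 / 9)
  expect_equal(spearman_scc(c(1, 2, 3, 3), c(2, 1, 4, 4)),
               oracle_spearman(c(1, 2, 3, 3), c(2, 1, 4, 4)),
               tolerance = 1e-14)
  # invariance under strictly monotone transforms
  withr::local_seed(2)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(spearman_scc(x, y), spearman_scc(exp(x), y^3 + 5 * y))
  # zero rank variance -> undefined marker
  expect_true(is.na(spearman_scc(rep(1, 5), 1:5)))
  expect_error(spearman_scc(1:2, 1:2), "at least 3")
})

test_that("scc_pvalue follows the t approximation with exact limits", {
  expect_equal(scc_pvalue(0, 100), 1)
  expect_equal(scc_pvalue(1, 50), 0)
  expect_equal(scc_pvalue(-1, 50), 0)
  # independent t-CDF evaluation
  s <- 0.5; n <- 100
  expect_equal(scc_pvalue(s, n),
               2 * pt(s * sqrt((n - 2) / (1 - s^2)), n - 2,
                      lower.tail = FALSE),
               tolerance = 1e-14)
  expect_error(scc_pvalue(0.3, 2), ">= 3")
})

test_that("redundancy pruning is a deterministic greedy pass per tissue", {
  withr::local_seed(4)
  g <- sprintf("g%04d", 1:300)
  base <- rnorm(300)
  mk <- function(id, vals) tas(g, vals, id = id, tissue = "a")
  # A ~ B strongly, B ~ C strongly, A ~ C weakly (greedy keeps A and C)
  e1 <- rnorm(300)
  a <- base
  b <- 0.8 * base + e1          # corr(A, B) ~ 0.62
  cc <- 2 * e1 + rnorm(300)     # corr(B, C) ~ 0.7, corr(A, C) ~ 0
  lib <- tas_library(list(mk("A", a), mk("B", b), mk("C", cc)))
  sAB <- spearman_scc(a, b); sBC <- spearman_scc(b, cc)
  sAC <- spearman_scc(a, cc)
  expect_gte(sAB, 0.5); expect_gte(sBC, 0.5); expect_lt(sAC, 0.5)
  pruned <- prune_redundant(lib, scc_cut = 0.5, min_overlap = 100)
  expect_identical(pruned$meta$id, c("A", "C"))
  # exact duplicate: second removed
  dup <- tas_library(list(mk("A", a), mk("Adup", a)))
  expect_identical(prune_redundant(dup, min_overlap = 100)$meta$id, "A")
  # all dissimilar: unchanged
  ind <- tas_library(lapply(1:4, function(i)
    mk(paste0("I", i), rnorm(300))))
  expect_equal(length(prune_redundant(ind, min_overlap = 100)), 4)
  # postcondition: all retained same-tissue pairs below the cut
  big <- tas_library(lapply(1:8, function(i)
    mk(paste0("M", i), 0.5 * base + rnorm(300))))
  kept <- prune_redundant(big, min_overlap = 100)
  ids <- kept$meta$id
  if (length(ids) > 1) {
    for (i in 2:length(ids)) for (j in 1:(i - 1)) {
      expect_lt(spearman_scc(kept$members[[ids[i]]]$log2fc,
                             kept$members[[ids[j]]]$log2fc), 0.5)
    }
  }
})

test_that("library matching applies the inclusive |SCC| >= 0.1 rule", {
  g <- sprintf("g%04d", 1:200)
  q <- tas(g, seq_along(g), id = "q", tissue = "a")
  # construct members with exact SCCs against the query ranks
  mk_rho <- function(rho, id) {
    # mixture on ranks then jitter-free: use exact permutation structure
    n <- length(g)
    z <- qnorm((seq_len(n) - 0.5) / n)
    r <- 2 * sin(pi * rho / 6)
    withr::with_seed(8, tas(g, r * z + sqrt(1 - r^2) * rnorm(n),
                            id = id, tissue = "a"))
  }
  lib <- tas_library(list(mk_rho(0.4, "hit"), mk_rho(0, "null"),
                          tas(g[1:50], rnorm(50), id = "tiny", tissue = "a"),
                          tas(g, rnorm(200), id = "other", tissue = "b")))
  expect_message(hits <- match_library(q, lib, min_overlap = 100),
                 "skipped 1")
  expect_setequal(hits$library_id, c("hit", "null"))  # same-tissue only
  expect_true(hits$significant[hits$library_id == "hit"])
  expect_equal(hits$n_shared, c(200, 200))
  # boundary: |SCC| exactly at threshold is a hit; below is not
  fake <- tibble::tibble(scc = c(0.1, -0.1, 0.05))
  expect_identical(abs(fake$scc) >= 0.1, c(TRUE, TRUE, FALSE))
  got <- match_library(q, lib, scc_threshold = abs(
    hits$scc[hits$library_id == "hit"]), min_overlap = 100)
  expect_true(got$significant[got$library_id == "hit"])
  # empty library for the tissue warns and returns an empty result
  qb <- tas(g, rnorm(200), id = "qb", tissue = "nowhere")
  expect_warning(none <- match_library(qb, lib), "no library members")
  expect_equal(nrow(none), 0)
})

test_that("match_library null false-positive rate follows the analytic tail", {
  withr::local_seed(6)
  n <- 400
  g <- sprintf("g%04d", 1:n)
  trials <- 0L; fps <- 0L
  for (s in 1:8) {
    cfg <- sim_config(seed = s, tas_library_size = 60, tas_rho = 0,
                      tas_correlated_fraction = 0)
    q <- tas(g, rnorm(n), id = "q", tissue = "a")
    lib <- simulate_tas_library(cfg, q)
    hits <- match_library(q, lib$library, min_overlap = 100)
    trials <- trials + nrow(hits)
    fps <- fps + sum(hits$significant)
  }
  t0 <- 0.1 * sqrt((n - 2) / (1 - 0.01))
  tail_prob <- 2 * (1 - pt(t0, n - 2))
  expect_lt(abs(fps / trials - tail_prob),
            3 * sqrt(tail_prob * (1 - tail_prob) / trials) + 0.01)
})

test_that("PTSP aggregation votes, tests and respects the tie rule", {
  mk_hits <- function(scc, outcome, tissue = "heart") {
    tibble::tibble(tissue = tissue, scc = scc, outcome = outcome,
                   significant = TRUE, label_path = outcome)
  }
  # 8 beneficial positive hits: protective with sign p = 2 * (1/2)^8
  h <- mk_hits(rep(0.3, 8), rep("beneficial", 8))
  call <- ptsp_aggregate(h)
  expect_identical(call$verdict, "estrus-protective")
  expect_equal(call$sign_test_p, 2 * (1 / 2)^8)
  expect_equal(call$protective_votes, 8)
  # tie -> indeterminate
  tie <- mk_hits(c(0.3, 0.3, 0.3, -0.3, -0.3, -0.3),
                 rep(c("beneficial", "deleterious"), each = 3))
  # beneficial+positive = protective; deleterious+negative = protective...
  # build a true tie: 3 protective, 3 harmful
  tie <- dplyr::bind_rows(mk_hits(rep(0.3, 3), rep("beneficial", 3)),
                          mk_hits(rep(0.3, 3), rep("deleterious", 3)))
  expect_identical(ptsp_aggregate(tie)$verdict, "indeterminate")
  # antisymmetry: negating all SCCs flips the verdict
  flipped <- h; flipped$scc <- -flipped$scc
  expect_identical(ptsp_aggregate(flipped)$verdict, "diestrus-protective")
  # reproductive tissues excluded by default, kept on request
  ov <- mk_hits(rep(0.3, 4), rep("beneficial", 4), tissue = "ovary")
  expect_equal(nrow(ptsp_aggregate(ov)), 0)
  expect_equal(nrow(ptsp_aggregate(ov, include_reproductive = TRUE)), 1)
  # outcome "none" never votes
  noisy <- dplyr::bind_rows(h, mk_hits(rep(-0.5, 3), rep("none", 3)))
  expect_equal(ptsp_aggregate(noisy)$protective_votes, 8)
})

test_that("label hierarchy counts satisfy the tree invariant", {
  g <- sprintf("g%03d", 1:120)
  lib <- tas_library(list(
    tas(g, rnorm(120), id = "m1", tissue = "a", outcome = "deleterious",
        label_path = c("deleterious", "disease", "cancer")),
    tas(g, rnorm(120), id = "m2", tissue = "a", outcome = "deleterious",
        label_path = c("deleterious", "disease")),
    tas(g, rnorm(120), id = "m3", tissue = "a", outcome = "beneficial",
        label_path = c("beneficial", "lifestyle"))))
  hits <- tibble::tibble(
    library_id = "m1", tissue = "a", scc = 0.4, significant = TRUE,
    outcome = "deleterious", label_path = "deleterious/disease/cancer")
  s <- label_hierarchy_summary(hits, lib)
  pos <- dplyr::filter(s, group == "positive")
  expect_equal(nrow(pos), 3)            # one count at each prefix depth
  expect_true(all(pos$n == 1))
  bg <- dplyr::filter(s, group == "background")
  # parent count equals the sum over children
  expect_equal(bg$n[bg$prefix == "deleterious/disease"],
               bg$n[bg$prefix == "deleterious/disease/cancer"] + 1)
  expect_equal(bg$n[bg$prefix == "deleterious"], 2)
  # empty hit set: background only
  s0 <- label_hierarchy_summary(hits[0, ], lib)
  expect_setequal(unique(s0$group), "background")
})
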