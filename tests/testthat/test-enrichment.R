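test_that("hypergeometric tail matches combinatorial identities", {
  # all 5 draws annotated: single term 1 / C(20,5)
  expect_equal(hypergeom_p(5, 5, 5, 20), 1 / choose(20, 5),
               tolerance = 1e-15)
  expect_equal(hypergeom_p(0, 3, 4, 10), 1)
  manual <- sum(vapply(2:3, function(j) {
    choose(3, j) * choose(7, 4 - j) / choose(10, 4)
  }, numeric(1)))
  expect_equal(hypergeom_p(2, 3, 4, 10), manual, tolerance = 1e-14)
  expect_error(hypergeom_p(4, 3, 4, 10), "inconsistent")
  expect_error(hypergeom_p(1, 11, 4, 10), "inconsistent")
})

test_that("hypergeometric tail agrees with exhaustive draw enumeration", {
  # brute force: enumerate every n-subset of a universe of N
  brute_tail <- function(k, K, n, N) {
    draws <- utils::combn(N, n)
    hits <- colSums(draws <= K) # the first K elements are "annotated"
    mean(hits >= k)
  }
  set.seed(13)
  for (i in 1:20) {
    N <- sample(5:12, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_p(k, K, n, N), brute_tail(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the hand-worked step-up and preserves decisions on re-application", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(3)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # step-up adjusted values are not a literal fixed point of the procedure
  # (p = (0.1, 0.9) maps to (0.2, 0.9) then (0.4, 0.9)); re-application can
  # only inflate, so it never creates new rejections
  readj <- bh_adjust(adj)
  expect_true(all(readj >= adj - 1e-15))
  expect_equal(bh_adjust(c(0.1, 0.9)), c(0.2, 0.9))
  expect_equal(bh_adjust(c(0.2, 0.9)), c(0.4, 0.9))
  # monotone in the sorted input
  o <- order(p)
  expect_true(all(diff(adj[o]) >= -1e-15))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

enrich_fixture <- function() {
  list(pwA = paste0("g", 1:5), pwB = paste0("g", 6:10),
       pwC = paste0("h", 1:8))
}

test_that("enrich composes hypergeom_p with BH over tested pathways", {
  coll <- enrich_fixture()
  res <- enrich(paste0("g", 1:5), coll)
  expect_equal(res$pathway[1], "pwA")
  expect_equal(res$N[1], 18)
  row <- res[res$pathway == "pwA", ]
  expect_equal(row$p_raw, hypergeom_p(row$k, row$K, row$n, row$N))
  expect_true(all(res$p_adj >= res$p_raw))

  expect_equal(nrow(enrich(character(0), coll)), 0)
  # default universe absorbs the query; an explicit universe drops outsiders
  expect_warning(
    res2 <- enrich(c("g1", "zz"), coll,
                   universe = unlist(coll, use.names = FALSE)),
    "outside universe")
  expect_equal(unique(res2$n), 1)
  expect_error(enrich("g1", coll, universe = character(0)), "empty universe")
})

test_that("filter_pathways applies strict count and name exclusions", {
  res <- data.frame(pathway = c("osteo path", "viral infection", "big path"),
                    k = c(12, 40, 13), K = 50, n = 60, N = 500,
                    p_raw = 1e-4, p_adj = 1e-3)
  out <- filter_pathways(res, min_count = 12)
  expect_setequal(out$pathway, c("viral infection", "big path"))
  out2 <- filter_pathways(res, min_count = 12, exclusion_terms = "viral")
  expect_equal(out2$pathway, "big path")
  out3 <- filter_pathways(res, min_count = 0)
  expect_equal(nrow(out3), 3)
})

test_that("coverage and reference proportions follow the set arithmetic", {
  coll <- c(enrich_fixture(),
            list(pwD = paste0("g", c(1:3, 6:8)), pwE = paste0("h", 1:4)))
  genes <- paste0("g", 1:10)
  expect_equal(pathway_coverage(genes, genes, coll), 1)
  # motif genes hitting only pwA-relevant genes cover a strict subset
  cov <- pathway_coverage(paste0("g", 1:5), genes, coll)
  expect_gte(cov, 0)
  expect_lte(cov, 1)
  expect_error(pathway_coverage(character(0), genes, coll), "non-empty")
  expect_error(pathway_coverage("h1", "h1", coll, alpha = 1e-12),
               "no significant pathway")

  expect_equal(
    reference_pathway_proportion(genes, genes, genes, coll), 1)
  expect_error(
    reference_pathway_proportion("g1", "h1", paste0("g", 6:10), coll,
                                 alpha = 1e-9),
    "empty reference")
})

test_that("constructed 4-of-5 shared significant pathways give coverage 0.8", {
  # five pathways significant for the full network; motif genes recover 4
  coll <- lapply(1:5, function(i) sprintf("m%d_%d", i, 1:6))
  names(coll) <- paste0("pw", 1:5)
  decoys <- lapply(1:5, function(i) sprintf("z%d_%d", i, 1:20))
  names(decoys) <- paste0("decoy", 1:5)
  coll <- c(coll, decoys)
  ct_genes <- unlist(coll[1:5], use.names = FALSE)
  frm_genes <- unlist(coll[1:4], use.names = FALSE)
  expect_equal(pathway_coverage(frm_genes, ct_genes, coll, alpha = 0.05),
               0.8)
})

test_that("high-reliability sets use strict above-mean membership", {
  d <- data.frame(gene = c("a", "b", "c"), relevance_score = c(2, 4, 6),
                  n_evidence = c(1, 1, 7))
  hs <- high_reliable_sets(d)
  expect_equal(hs$by_relevance, "c")
  expect_equal(hs$by_evidence, "c")
  expect_equal(unname(hs$thresholds["relevance"]), 4)

  allsame <- data.frame(gene = c("a", "b"), relevance_score = c(3, 3),
                        n_evidence = c(2, 2))
  expect_length(high_reliable_sets(allsame)$by_relevance, 0)
  one <- data.frame(gene = "a", relevance_score = 3, n_evidence = 2)
  expect_length(high_reliable_sets(one)$by_relevance, 0)
})

test_that("frm_disease_summary compares motif genes against the table", {
  set.seed(2)
  d <- data.frame(gene = paste0("g", 1:40),
                  relevance_score = c(runif(30, 0, 4), runif(10, 10, 20)),
                  n_evidence = rpois(40, 3))
  top <- d$gene[31:40]
  s <- frm_disease_summary(top, d)
  expect_equal(s$n_annotated, 10)
  expect_gt(s$mean_relevance, s$table_mean_relevance)
  expect_lte(s$p_vs_high_relevance, 1)
  expect_error(frm_disease_summary("nope", d), "no motif gene")

  # motif set equal to the high-reliable set: identical means
  hs <- high_reliable_sets(d)
  s2 <- frm_disease_summary(hs$by_relevance, d)
  expect_equal(s2$mean_relevance,
               mean(d$relevance_score[d$gene %in% hs$by_relevance]))
})
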