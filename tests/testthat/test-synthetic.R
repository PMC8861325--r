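test_that("planted networks honour the block structure and seed", {
  spec <- planted_spec(n_modules = 2, components_per_module = 3,
                       targets_per_module = 5, p_in = 1, p_out = 0)
  pl <- generate_planted_network(spec, seed = 1)
  # p_in = 1, p_out = 0: two complete bipartite blocks
  expect_equal(nrow(pl$network$edges), 2 * 3 * 5)
  for (e in seq_len(nrow(pl$network$edges))) {
    cm <- pl$truth[paste0("C:", pl$network$edges$component[e])]
    tm <- pl$truth[paste0("T:", pl$network$edges$target[e])]
    expect_equal(unname(cm), unname(tm))
  }
  # determinism
  pl2 <- generate_planted_network(spec, seed = 1)
  expect_identical(pl$network$edges, pl2$network$edges)
  # with stochastic edges, different seeds give different networks
  expect_false(identical(
    generate_planted_network(planted_spec(), seed = 1)$network$edges,
    generate_planted_network(planted_spec(), seed = 2)$network$edges))
  # spec validation
  expect_error(planted_spec(p_in = 0.3, p_out = 0.5), "p_out < p_in")
  expect_error(planted_spec(n_modules = 0), "at least 1")
})

test_that("expected edge count matches the binomial mean within 3 sigma", {
  spec <- planted_spec()
  n_within <- spec$n_modules * spec$components_per_module *
    spec$targets_per_module
  n_total <- (spec$n_modules * spec$components_per_module) *
    (spec$n_modules * spec$targets_per_module)
  n_across <- n_total - n_within
  mu <- n_within * spec$p_in + n_across * spec$p_out
  sigma <- sqrt(n_within * spec$p_in * (1 - spec$p_in) +
                  n_across * spec$p_out * (1 - spec$p_out))
  counts <- vapply(1:50, function(s) {
    nrow(generate_planted_network(spec, seed = s)$network$edges)
  }, numeric(1))
  # isolated-node rewiring can only add a handful of edges
  expect_lt(abs(mean(counts) - mu), 3 * sigma / sqrt(50) + 2)
  expect_true(all(vapply(1:5, function(s) {
    net <- generate_planted_network(spec, seed = s)$network
    all(table(net$edges$component) >= 1) && all(table(net$edges$target) >= 1)
  }, logical(1))))
})

test_that("disease tables carry the planted enrichment", {
  pl <- generate_planted_network(planted_spec(), seed = 3)
  # no effect: same marginal law -> means close over many genes
  d0 <- generate_disease_table(pl$truth, enriched_modules = 1,
                               effect_size = 0, seed = 4)
  expect_equal(sort(d0$gene), sort(sub("^T:", "",
    names(pl$truth)[startsWith(names(pl$truth), "T:")])))
  expect_error(generate_disease_table(pl$truth, enriched_modules = 99),
               "unknown module")
  # strong effect separates the means in nearly every seed
  hits <- vapply(1:20, function(s) {
    d <- generate_disease_table(pl$truth, enriched_modules = 1,
                                effect_size = 8, seed = s)
    enr <- d$gene %in% sub("^T:", "", names(pl$truth)[pl$truth == 1 &
                                          startsWith(names(pl$truth), "T:")])
    mean(d$relevance_score[enr]) > mean(d$relevance_score[!enr])
  }, logical(1))
  expect_gte(sum(hits), 19)
  # empty enriched set: all baseline, determinism
  d1 <- generate_disease_table(pl$truth, seed = 9)
  d2 <- generate_disease_table(pl$truth, seed = 9)
  expect_identical(d1, d2)
})

test_that("gene sets overlap planted modules as requested", {
  pl <- generate_planted_network(planted_spec(), seed = 5)
  sets <- generate_genesets(pl$truth, n_pathways = 12, overlap_frac = 1,
                            seed = 6)
  expect_length(sets, 12)
  mod1_targets <- sub("^T:", "", names(pl$truth)[pl$truth == 1 &
                                      startsWith(names(pl$truth), "T:")])
  expect_setequal(sets$module_pathway_01, mod1_targets)
  # decoy-only enrichment of module genes finds nothing significant
  nulls <- vapply(1:10, function(s) {
    decoys <- generate_genesets(pl$truth, n_pathways = 10, seed = s)
    decoys <- decoys[grepl("^decoy", names(decoys))]
    res <- enrich(mod1_targets, decoys)
    !any(res$p_adj < 0.05)
  }, logical(1))
  expect_gte(sum(nulls), 9)
})

test_that("compound tables plant an exact drug-like count", {
  tab <- generate_compound_table(10, druglike_frac = 0.3, seed = 2)
  res <- screen_table(tab)
  expect_equal(nrow(res$passed), 3)
  expect_true(all(nzchar(tab$planted_violation[!res$report$pass])))
  expect_equal(nrow(screen_table(
    generate_compound_table(8, 1, seed = 3))$passed), 8)
  expect_equal(nrow(screen_table(
    generate_compound_table(8, 0, seed = 3))$passed), 0)
  expect_identical(generate_compound_table(15, 0.4, seed = 7),
                   generate_compound_table(15, 0.4, seed = 7))
})

test_that("simulate_bundle writes a complete, reloadable fixture set", {
  dir <- withr::local_tempdir()
  b <- simulate_bundle(seed = 11, outdir = dir)
  expect_true(all(file.exists(unlist(b$paths))))
  net <- load_ct_network(b$paths$network)
  expect_identical(sort(paste(net$edges$component, net$edges$target)),
                   sort(paste(b$network$edges$component,
                              b$network$edges$target)))
  expect_s3_class(read_disease_table(b$paths$disease), "data.frame")
  expect_gt(length(read_gmt(b$paths$genesets)), 0)
  expect_equal(nrow(read_compound_table(b$paths$compounds)), 20)
})
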