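# Two triangles joined by a bridge edge: the standard worked example for
# the two-level codelength.
two_triangles <- function() {
  data.frame(from = c("a", "a", "b", "c", "d", "d", "e"),
             to = c("b", "c", "c", "d", "e", "f", "f"))
}

test_that("visit rates match closed forms", {
  # symmetric path: equal rates
  v <- visit_rates(data.frame(from = "c1", to = "t1"), tau = 0)
  expect_equal(unname(as.numeric(v)), c(0.5, 0.5))

  # star: p = deg / 2|E|
  v <- visit_rates(data.frame(from = c("c1", "c1"), to = c("t1", "t2")),
                   tau = 0)
  expect_equal(as.numeric(v[c("c1", "t1", "t2")]), c(0.5, 0.25, 0.25))

  # tau -> 1 limit is uniform
  ed <- two_triangles()
  v <- visit_rates(ed, tau = 0.999)
  expect_equal(unname(as.numeric(v)), rep(1 / 6, 6), tolerance = 1e-3)

  # tau = 0 needs a connected network
  disc <- data.frame(from = c("a", "c"), to = c("b", "d"))
  expect_error(visit_rates(disc, tau = 0), "tau > 0")
  expect_silent(visit_rates(disc, tau = 0.15))
  expect_error(visit_rates(ed, tau = 1), "tau")
})

test_that("visit rates with teleportation sum to 1 and stay positive", {
  set.seed(5)
  for (i in 1:10) {
    net <- random_bipartite_net(nc = 4, nt = 6, p = 0.4)
    v <- visit_rates(net, tau = 0.15)
    expect_equal(sum(v), 1, tolerance = 1e-10)
    expect_true(all(as.numeric(v) >= 0))
  }
})

test_that("one-module codelength equals the visit-rate entropy", {
  ed <- two_triangles()
  v <- visit_rates(ed, tau = 0)
  cl <- codelength(ed, rep(1, 6), v = v)
  expected <- 4 * (1 / 7) * log2(7) + 2 * (3 / 14) * log2(14 / 3)
  expect_equal(cl$L, expected, tolerance = 1e-12)
  expect_equal(cl$q_total, 0)
  expect_equal(cl$L, entropy_bits(as.numeric(v)), tolerance = 1e-12)

  # the two-triangle split strictly improves on one module
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  cl2 <- codelength(ed, memb, v = v)
  expect_lt(cl2$L, cl$L)
  # assembly invariant: L = q H(Q) + sum p_circ H(P)
  expect_equal(cl2$L,
               cl2$q_total * cl2$HQ + sum(cl2$p_circ * cl2$HP),
               tolerance = 1e-12)
  expect_true(all(c(cl2$HQ, cl2$HP) >= 0))
})

test_that("codelength is invariant under node and module relabeling", {
  ed <- two_triangles()
  v <- visit_rates(ed, tau = 0.15)
  memb <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  L1 <- codelength(ed, memb, v = v)$L
  # swap module ids
  L2 <- codelength(ed, c(a = 7, b = 7, c = 7, d = 3, e = 3, f = 3), v = v)$L
  expect_equal(L1, L2, tolerance = 1e-12)
  # relabel nodes
  ed2 <- data.frame(from = paste0("x_", ed$from), to = paste0("x_", ed$to))
  memb2 <- stats::setNames(memb, paste0("x_", names(memb)))
  L3 <- codelength(ed2, memb2, v = visit_rates(ed2, tau = 0.15))$L
  expect_equal(L1, L3, tolerance = 1e-12)
  # missing node errors
  expect_error(codelength(ed, memb[-1], v = v), "missing")
})

test_that("optimizer recovers planted blocks and never beats one module badly", {
  # two dense blocks joined by one bridge edge
  blocks <- rbind(
    expand.grid(from = paste0("a", 1:3), to = paste0("b", 1:2)),
    expand.grid(from = paste0("x", 1:3), to = paste0("y", 1:2)),
    data.frame(from = "a1", to = "y1")
  )
  blocks$from <- as.character(blocks$from)
  blocks$to <- as.character(blocks$to)
  opt <- optimize_partition(blocks, tau = 0.15, seed = 3)
  memb <- opt$membership
  expect_equal(opt$report$m, 2)
  expect_length(unique(memb[c("a1", "a2", "a3", "b1", "b2")]), 1)
  expect_length(unique(memb[c("x1", "x2", "x3", "y1", "y2")]), 1)

  one_L <- codelength(blocks, rep(1, 10), tau = 0.15)$L
  expect_lte(opt$report$L, one_L)
})

test_that("optimizer matches the exhaustive minimum on small graphs", {
  set.seed(17)
  parts5 <- enumerate_set_partitions(5)
  for (i in 1:6) {
    ed <- random_connected_graph(5, p = 0.55)
    v <- visit_rates(ed, tau = 0.15)
    best <- min(apply(parts5, 1, function(m) {
      codelength(ed, stats::setNames(m, sort(unique(c(ed$from, ed$to)))),
                 v = v)$L
    }))
    opt <- optimize_partition(ed, tau = 0.15, seed = i)
    expect_equal(opt$report$L, best, tolerance = 1e-9)
  }
  # K_{2,2}: no split improves on one module
  k22 <- ct_network(expand.grid(component = c("c1", "c2"),
                                target = c("t1", "t2"),
                                stringsAsFactors = FALSE))
  opt <- optimize_partition(k22, tau = 0.15, seed = 1)
  expect_equal(opt$report$m, 1)
})

test_that("optimizer is deterministic for a fixed seed", {
  net <- generate_planted_network(planted_spec(), seed = 4)$network
  o1 <- optimize_partition(net, seed = 42)
  o2 <- optimize_partition(net, seed = 42)
  expect_identical(o1$membership, o2$membership)
  expect_equal(o1$report$L, o2$report$L)
})
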