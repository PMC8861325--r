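#' @title Two-level map equation on undirected networks
#' @description
#' The module-detection objective used throughout this package is the
#' two-level map equation: a partition M of the nodes into m modules is
#' scored by the expected per-step description length of a random walk
#' under a two-level (index + per-module) Huffman codebook,
#'
#'   L(M) = q * H(Q) + sum_i p_circ_i * H(P_i),
#'
#' where q_i is the per-step probability of exiting module i, q = sum q_i,
#' H(Q) the entropy of the normalized exit rates (the index codebook),
#' p_circ_i = q_i + sum of visit rates inside module i, and H(P_i) the
#' entropy of the within-module codebook (exit word plus member nodes).
#' Lower codelength means the partition compresses the walk better.
#' Logarithms are base 2 (bits); 0 log 0 is 0.
#' @name map_equation
NULL

# ---- internal walk-graph representation ------------------------------------
# Undirected simple graph stored as directed edge arrays (both directions):
# nodes (chr), n, ei -> ej (int indices), deg (int per node).

walk_graph <- function(edges, nodes = NULL) {
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  if (any(from == to)) stop("self-loops not supported")
  if (is.null(nodes)) nodes <- sort(unique(c(from, to)))
  i <- match(from, nodes)
  j <- match(to, nodes)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint not in node set")
  key <- paste(pmin(i, j), pmax(i, j))
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    i <- i[keep]; j <- j[keep]
  }
  n <- length(nodes)
  ei <- c(i, j)
  ej <- c(j, i)
  deg <- tabulate(ei, nbins = n)
  structure(list(nodes = nodes, n = n, ei = ei, ej = ej, deg = deg,
                 n_edges = length(i)),
            class = "walk_graph")
}

as_walk_graph <- function(x) {
  if (inherits(x, "walk_graph")) return(x)
  if (inherits(x, "ct_network")) {
    return(walk_graph(ct_walk_edges(x), nodes = ct_node_ids(x)))
  }
  if (is.data.frame(x)) return(walk_graph(x))
  stop("cannot interpret object as a graph")
}

# Connected components by BFS over the edge arrays.
walk_components <- function(g) {
  comp <- integer(g$n)
  adj <- split(g$ej, g$ei)
  cur <- 0L
  for (s in seq_len(g$n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- adj[[as.character(v)]]
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# ---- visit rates -----------------------------------------------------------

#' Stationary visit rates of a random walk with teleportation
#'
#' The walker follows a uniformly random edge with probability `1 - tau`
#' and teleports to a uniformly random node with probability `tau`. With
#' `tau = 0` on a connected undirected network the stationary distribution
#' has the closed form `deg(a) / (2 |E|)`; with `tau > 0` the distribution
#' is obtained by power iteration to an L1 tolerance of 1e-10. Teleportation
#' keeps the walk well-posed on disconnected C-T networks.
#'
#' @param net a `ct_network`, a `from`/`to` edge data.frame, or an internal
#'   walk graph.
#' @param tau teleportation probability in `[0, 1)` (default 0.15).
#' @return named numeric vector of visit rates summing to 1 (class
#'   `visit_distribution`, with `tau` attribute).
#' @export
visit_rates <- function(net, tau = 0.15) {
  g <- as_walk_graph(net)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau >= 1) {
    stop("tau must lie in [0, 1)")
  }
  if (tau == 0) {
    if (any(g$deg == 0L) || max(walk_components(g)) > 1L) {
      stop("network is disconnected; use tau > 0 for a well-defined walk")
    }
    p <- g$deg / (2 * g$n_edges)
  } else {
    n <- g$n
    p <- rep(1 / n, n)
    dangling <- g$deg == 0L
    w <- ifelse(g$deg[g$ei] > 0L, 1 / g$deg[g$ei], 0)
    for (iter in seq_len(10000L)) {
      flow <- numeric(n)
      contrib <- p[g$ei] * w
      agg <- rowsum(contrib, g$ej)
      flow[as.integer(rownames(agg))] <- agg[, 1L]
      dang_mass <- sum(p[dangling])
      p_new <- (1 - tau) * (flow + dang_mass / n) + tau / n
      if (sum(abs(p_new - p)) < 1e-10) {
        p <- p_new
        break
      }
      p <- p_new
    }
    p <- p / sum(p)
  }
  structure(stats::setNames(p, g$nodes), class = "visit_distribution",
            tau = tau)
}

# ---- codelength ------------------------------------------------------------

plogp <- function(x) {
  y <- numeric(length(x))
  pos <- x > 0
  y[pos] <- x[pos] * log2(x[pos])
  y
}

# membership: integer vector (contiguous ids from 1) aligned with g$nodes.
# Returns per-module exit rates q_i including teleportation flow.
module_exit_rates <- function(g, membership, p, tau) {
  m <- max(membership)
  n <- g$n
  module_size <- tabulate(membership, nbins = m)
  q <- numeric(m)
  if (tau < 1) {
    cross <- membership[g$ei] != membership[g$ej]
    if (any(cross)) {
      contrib <- (1 - tau) * p[g$ei[cross]] / g$deg[g$ei[cross]]
      agg <- rowsum(contrib, membership[g$ei[cross]])
      q[as.integer(rownames(agg))] <- agg[, 1L]
    }
    dangling <- which(g$deg == 0L)
    if (length(dangling) > 0L) {
      # a dangling node's non-teleport step is a uniform jump
      contrib <- (1 - tau) * p[dangling] *
        (n - module_size[membership[dangling]]) / n
      agg <- rowsum(contrib, membership[dangling])
      q[as.integer(rownames(agg))] <- q[as.integer(rownames(agg))] + agg[, 1L]
    }
  }
  if (tau > 0) {
    pm <- rowsum(p, membership)[, 1L]
    q <- q + tau * pm * (n - module_size) / n
  }
  q
}

#' Map-equation codelength of a partition
#'
#' Assembles every term of the two-level codelength: per-module exit rates
#' `q_i` (including teleportation flow leaving the module), total exit rate
#' `q`, index-codebook entropy `H(Q)`, per-module codebook usage
#' `p_circ_i = q_i + sum of member visit rates` and entropy `H(P_i)`, and
#' the total `L = q H(Q) + sum_i p_circ_i H(P_i)` in bits per step. A
#' one-module partition has `q = 0` and `L` equal to the entropy of the
#' visit rates.
#'
#' @param net network accepted by [visit_rates()].
#' @param membership module assignment: named (by node) or positionally
#'   aligned vector; coerced to contiguous integer module ids.
#' @param v visit distribution from [visit_rates()]; computed at `tau` if
#'   missing.
#' @param tau teleportation rate used when `v` is missing (default 0.15).
#' @return list of class `codelength_report`: `L`, `q_exit`, `q_total`,
#'   `HQ`, `p_circ`, `HP`, `m`, `membership`.
#' @export
codelength <- function(net, membership, v = NULL, tau = 0.15) {
  g <- as_walk_graph(net)
  memb <- normalize_membership(g, membership)
  if (is.null(v)) v <- visit_rates(g, tau) else tau <- attr(v, "tau")
  p <- as.numeric(v)[match(g$nodes, names(v))]
  if (anyNA(p)) stop("visit distribution does not cover the network")

  m <- max(memb)
  q <- module_exit_rates(g, memb, p, tau)
  q_total <- sum(q)
  HQ <- if (q_total > 0) -sum(plogp(q / q_total)) else 0
  pm <- rowsum(p, memb)[, 1L]
  p_circ <- q + pm
  HP <- vapply(seq_len(m), function(i) {
    denom <- p_circ[i]
    if (denom <= 0) return(0)
    inside <- p[memb == i]
    -sum(plogp(c(q[i], inside) / denom))
  }, numeric(1))
  L <- q_total * HQ + sum(p_circ * HP)
  structure(
    list(L = L, q_exit = q, q_total = q_total, HQ = HQ,
         p_circ = p_circ, HP = HP, m = m,
         membership = stats::setNames(memb, g$nodes)),
    class = "codelength_report"
  )
}

normalize_membership <- function(g, membership) {
  if (!is.null(names(membership))) {
    idx <- match(g$nodes, names(membership))
    if (anyNA(idx)) {
      stop(sprintf("node(s) missing from partition: %s",
                   paste(utils::head(g$nodes[is.na(idx)], 3), collapse = ", ")))
    }
    membership <- membership[idx]
  } else if (length(membership) != g$n) {
    stop("membership length does not match node count")
  }
  as.integer(factor(membership, levels = unique(membership)))
}

# ---- partition search ------------------------------------------------------

#' Minimize the map-equation codelength over partitions
#'
#' Seeded multi-restart local search in the Louvain style: starting from
#' singleton modules, repeated sweeps move each node (in shuffled order) to
#' the neighbouring module that most lowers the codelength, interleaved
#' with greedy merges of adjacent modules, until no move improves. The best
#' partition over all restarts is returned. Ties are broken toward the
#' lower module id, so results are reproducible for a fixed seed.
#'
#' @param net network accepted by [visit_rates()].
#' @param v optional precomputed visit distribution.
#' @param tau teleportation rate if `v` is missing (default 0.15).
#' @param seed integer RNG seed.
#' @param n_restarts number of restarts (default 8).
#' @param max_sweeps cap on move sweeps per restart (default 50).
#' @return list with `membership` (named, contiguous ids, relabeled in
#'   first-appearance order) and `report` (the [codelength()] of the best
#'   partition).
#' @export
optimize_partition <- function(net, v = NULL, tau = 0.15, seed = 1L,
                               n_restarts = 8L, max_sweeps = 50L) {
  g <- as_walk_graph(net)
  if (g$n < 2L) stop("need at least 2 nodes")
  if (is.null(v)) v <- visit_rates(g, tau) else tau <- attr(v, "tau")
  p <- as.numeric(v)[match(g$nodes, names(v))]

  adj <- vector("list", g$n)
  split_adj <- split(g$ej, g$ei)
  adj[as.integer(names(split_adj))] <- split_adj

  eval_L <- function(memb) {
    memb <- as.integer(factor(memb, levels = sort(unique(memb))))
    codelength_fast(g, memb, p, tau)
  }

  best_memb <- NULL
  best_L <- Inf
  for (r in seq_len(n_restarts)) {
    set.seed(as.integer(seed) + r - 1L)
    memb <- seq_len(g$n)
    cur_L <- eval_L(memb)
    repeat {
      improved <- FALSE
      for (vtx in sample.int(g$n)) {
        cands <- sort(unique(c(memb[adj[[vtx]]], memb[vtx])))
        if (length(cands) <= 1L) next
        Ls <- vapply(cands, function(mod) {
          mm <- memb
          mm[vtx] <- mod
          eval_L(mm)
        }, numeric(1))
        k <- which.min(Ls) # which.min takes the first (lowest id) on ties
        if (Ls[k] < cur_L - 1e-12) {
          memb[vtx] <- cands[k]
          cur_L <- Ls[k]
          improved <- TRUE
        }
      }
      # merge pass over adjacent module pairs
      repeat {
        mods <- sort(unique(memb))
        if (length(mods) <= 1L) break
        pair_i <- memb[g$ei]
        pair_j <- memb[g$ej]
        keep <- pair_i < pair_j
        pairs <- unique(cbind(pair_i[keep], pair_j[keep]))
        merged <- FALSE
        if (nrow(pairs) > 0L) {
          Ls <- vapply(seq_len(nrow(pairs)), function(k) {
            mm <- memb
            mm[mm == pairs[k, 2L]] <- pairs[k, 1L]
            eval_L(mm)
          }, numeric(1))
          k <- which.min(Ls)
          if (Ls[k] < cur_L - 1e-12) {
            memb[memb == pairs[k, 2L]] <- pairs[k, 1L]
            cur_L <- Ls[k]
            improved <- TRUE
            merged <- TRUE
          }
        }
        if (!merged) break
      }
      max_sweeps <- max_sweeps - 1L
      if (!improved || max_sweeps <= 0L) break
    }
    if (cur_L < best_L - 1e-12) {
      best_L <- cur_L
      best_memb <- memb
    }
  }
  memb <- as.integer(factor(best_memb, levels = unique(best_memb)))
  report <- codelength(g, memb, v = structure(stats::setNames(p, g$nodes),
                                              class = "visit_distribution",
                                              tau = tau))
  list(membership = stats::setNames(memb, g$nodes), report = report)
}

# L only, skipping report assembly — the inner loop of the optimizer.
codelength_fast <- function(g, memb, p, tau) {
  m <- max(memb)
  q <- module_exit_rates(g, memb, p, tau)
  q_total <- sum(q)
  HQ <- if (q_total > 0) -sum(plogp(q / q_total)) else 0
  pm <- rowsum(p, memb)[, 1L]
  p_circ <- q + pm
  # sum_i p_circ_i H(P_i) = -sum_i [ plogp(q_i) + sum_{a in i} plogp(p_a)
  #                                  - p_circ_i log2 p_circ_i ]
  within <- -sum(plogp(q)) - sum(plogp(p)) + sum(plogp(p_circ))
  q_total * HQ + within
}
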