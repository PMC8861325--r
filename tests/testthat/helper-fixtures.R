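# Shared fixtures and independent oracles for the test suite.

# Independent Shannon entropy in bits (oracle for codelength identities).
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

# All set partitions of n elements as restricted-growth strings.
# enumerate_set_partitions(6) has Bell(6) = 203 rows.
enumerate_set_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_max) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_max + 1L)) {
      recurse(c(labels, lab), max(next_max, lab))
    }
  }
  recurse(integer(0), 0L)
  do.call(rbind, out)
}

# Small deterministic ct_network fixture used across files.
tiny_net <- function() {
  ct_network(data.frame(
    component = c("c1", "c1", "c2"),
    target = c("t1", "t2", "t1")
  ))
}

# Random connected undirected graph on n nodes as a from/to edge data.frame.
random_connected_graph <- function(n, p = 0.5) {
  repeat {
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p
    if (!any(keep)) next
    ed <- data.frame(from = paste0("n", pairs[1, keep]),
                     to = paste0("n", pairs[2, keep]))
    nodes <- paste0("n", seq_len(n))
    if (!all(nodes %in% c(ed$from, ed$to))) next
    # connectivity check by BFS
    adj <- lapply(nodes, function(v) {
      unique(c(ed$to[ed$from == v], ed$from[ed$to == v]))
    })
    names(adj) <- nodes
    seen <- nodes[1]
    frontier <- nodes[1]
    while (length(frontier) > 0) {
      nxt <- setdiff(unique(unlist(adj[frontier])), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    if (length(seen) == n) return(ed)
  }
}

# Random connected bipartite ct_network.
random_bipartite_net <- function(nc = 4, nt = 6, p = 0.5) {
  repeat {
    grid <- expand.grid(c = seq_len(nc), t = seq_len(nt))
    keep <- stats::runif(nrow(grid)) < p
    if (sum(keep) < nc + nt - 1) next
    ed <- data.frame(component = paste0("c", grid$c[keep]),
                     target = paste0("t", grid$t[keep]))
    if (length(unique(ed$component)) < nc || length(unique(ed$target)) < nt) next
    net <- ct_network(ed)
    g_ok <- tryCatch({
      visit_rates(net, tau = 0)
      TRUE
    }, error = function(e) FALSE)
    if (g_ok) return(net)
  }
}

# Three-component worked fixture for the Q-score chain.
qscore_fixture <- function() {
  list(
    target_sets = list(c1 = paste0("g", 1:5), c2 = paste0("g", 4:8),
                       c3 = "g9"),
    T = c(5L, 5L, 1L),
    t_all = paste0("g", 1:10)
  )
}
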