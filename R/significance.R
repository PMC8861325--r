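#' Degree-preserving rewiring of a bipartite edge set
#'
#' Randomizes a C-T network while preserving every node's degree, by
#' repeated double-edge swaps: two edges (c1,t1), (c2,t2) are replaced by
#' (c1,t2), (c2,t1) whenever the swap creates no duplicate edge. This is
#' the null model used for module significance.
#'
#' @param net a `ct_network`.
#' @param n_swaps number of attempted swaps (default 10 per edge).
#' @return a rewired `ct_network` with identical degree sequences.
#' @export
rewire_bipartite <- function(net, n_swaps = 10L * nrow(net$edges)) {
  stopifnot(inherits(net, "ct_network"))
  comp <- net$edges$component
  targ <- net$edges$target
  ne <- length(comp)
  if (ne < 2L) return(net)
  key <- function(a, b) paste(a, b, sep = "\r")
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(comp, targ)) assign(k, TRUE, envir = present)
  picks <- matrix(sample.int(ne, 2L * n_swaps, replace = TRUE), ncol = 2L)
  for (s in seq_len(n_swaps)) {
    a <- picks[s, 1L]; b <- picks[s, 2L]
    if (a == b) next
    if (comp[a] == comp[b] || targ[a] == targ[b]) next
    k1 <- key(comp[a], targ[b]); k2 <- key(comp[b], targ[a])
    if (exists(k1, envir = present, inherits = FALSE) ||
        exists(k2, envir = present, inherits = FALSE)) next
    rm(list = c(key(comp[a], targ[a]), key(comp[b], targ[b])), envir = present)
    tmp <- targ[a]; targ[a] <- targ[b]; targ[b] <- tmp
    assign(k1, TRUE, envir = present); assign(k2, TRUE, envir = present)
  }
  ct_network(data.frame(component = comp, target = targ,
                        stringsAsFactors = FALSE))
}

# Codelength saving of splitting one module out of the one-module partition.
module_saving <- function(g, members_idx, p, tau) {
  memb <- rep(1L, g$n)
  memb[members_idx] <- 2L
  if (all(memb == 2L) || all(memb == 1L)) return(0)
  one_L <- codelength_fast(g, rep(1L, g$n), p, tau)
  one_L - codelength_fast(g, as.integer(factor(memb)), p, tau)
}

#' Permutation significance of network modules
#'
#' For each module of a partition, the observed statistic is the codelength
#' saving of splitting that module out of the one-module partition. The
#' null distribution is obtained by degree-preserving bipartite rewiring
#' ([rewire_bipartite()]): the same node set is split out of each rewired
#' network and the saving recomputed. The p-value uses the add-one
#' estimator `p = (1 + #(null >= observed)) / (1 + n_perm)`. Modules of
#' size 1 get `p = 1` by convention (with a message).
#'
#' @param net a `ct_network`.
#' @param membership partition over the prefixed walk nodes (as returned by
#'   [optimize_partition()]).
#' @param tau teleportation rate (default 0.15).
#' @param n_perm number of permutations, at least 99 (default 199).
#' @param seed integer RNG seed.
#' @return data.frame of class `sdfm_table`: `module`, `n_components`,
#'   `n_targets`, `saving` (bits), `p_value`; attribute `members` holds the
#'   per-module node lists (original, unprefixed ids split into components
#'   and targets).
#' @export
module_significance <- function(net, membership, tau = 0.15, n_perm = 199L,
                                seed = 1L) {
  stopifnot(inherits(net, "ct_network"))
  if (!is.numeric(n_perm) || n_perm < 99) {
    stop("n_perm must be at least 99")
  }
  g <- as_walk_graph(net)
  memb <- normalize_membership(g, membership)
  p <- as.numeric(visit_rates(g, tau))
  m <- max(memb)
  obs <- vapply(seq_len(m), function(i) {
    module_saving(g, which(memb == i), p, tau)
  }, numeric(1))

  set.seed(as.integer(seed))
  exceed <- integer(m)
  sizes <- tabulate(memb, nbins = m)
  node_names <- g$nodes
  member_sets <- lapply(seq_len(m), function(i) node_names[memb == i])
  for (b in seq_len(n_perm)) {
    rnet <- rewire_bipartite(net)
    rg <- as_walk_graph(rnet)
    rp <- as.numeric(visit_rates(rg, tau))
    idx_map <- match(node_names, rg$nodes)
    for (i in seq_len(m)) {
      if (sizes[i] <= 1L) next
      sav <- module_saving(rg, idx_map[memb == i], rp, tau)
      if (sav >= obs[i]) exceed[i] <- exceed[i] + 1L
    }
  }
  pval <- (1 + exceed) / (1 + n_perm)
  if (any(sizes <= 1L)) {
    message(sprintf("%d singleton module(s) assigned p = 1 by convention",
                    sum(sizes <= 1L)))
    pval[sizes <= 1L] <- 1
  }
  members <- lapply(member_sets, function(nm) {
    list(components = sub("^C:", "", nm[startsWith(nm, "C:")]),
         targets = sub("^T:", "", nm[startsWith(nm, "T:")]))
  })
  out <- data.frame(
    module = seq_len(m),
    n_components = vapply(members, function(x) length(x$components), integer(1)),
    n_targets = vapply(members, function(x) length(x$targets), integer(1)),
    saving = obs,
    p_value = pval
  )
  attr(out, "members") <- members
  class(out) <- c("sdfm_table", "data.frame")
  out
}

#' Select significant different functional modes (SDFMs)
#'
#' Keeps modules with permutation `p < alpha` (strict), ordered by
#' codelength saving, largest first.
#'
#' @param modules an `sdfm_table` from [module_significance()].
#' @param alpha significance level (default 0.05).
#' @return the filtered, reordered `sdfm_table` (members attribute kept in
#'   step).
#' @export
select_sdfms <- function(modules, alpha = 0.05) {
  stopifnot(inherits(modules, "sdfm_table"))
  keep <- which(modules$p_value < alpha)
  keep <- keep[order(modules$saving[keep], decreasing = TRUE)]
  out <- modules[keep, , drop = FALSE]
  attr(out, "members") <- attr(modules, "members")[keep]
  class(out) <- c("sdfm_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Genes (targets) covered by a set of SDFMs/FRMs
#'
#' @param sdfms an `sdfm_table`.
#' @return character vector of unique target ids across the modules.
#' @export
sdfm_targets <- function(sdfms) {
  members <- attr(sdfms, "members")
  unique(unlist(lapply(members, `[[`, "targets"), use.names = FALSE))
}

#' Components covered by a set of SDFMs/FRMs
#'
#' @param sdfms an `sdfm_table`.
#' @return character vector of unique component ids across the modules.
#' @export
sdfm_components <- function(sdfms) {
  members <- attr(sdfms, "members")
  unique(unlist(lapply(members, `[[`, "components"), use.names = FALSE))
}
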