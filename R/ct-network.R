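#' Construct a bipartite component-target (C-T) network
#'
#' A C-T network links chemical components (e.g. herbal compounds) to the
#' protein targets they are predicted to act on. The graph is strictly
#' bipartite: every edge joins one component to one target. Node identifiers
#' are kept in two disjoint internal namespaces (prefixes `"C:"` and `"T:"`)
#' so that a component and a gene that happen to share a symbol never
#' collide.
#'
#' @param edges data.frame with columns `component` and `target` (and an
#'   optional positive `weight`, defaulting to 1). Duplicate rows are
#'   collapsed with a warning.
#' @param allow_isolated keep declared nodes with no edges (default FALSE).
#' @return An object of class `ct_network` with elements `components`,
#'   `targets` (character vectors of original ids) and `edges`
#'   (data.frame `component`, `target`, `weight`).
#' @export
ct_network <- function(edges, allow_isolated = FALSE) {
  stopifnot(is.data.frame(edges))
  if (!all(c("component", "target") %in% names(edges))) {
    stop("edges must have 'component' and 'target' columns")
  }
  if (nrow(edges) == 0L) stop("empty edge list")
  comp <- as.character(edges$component)
  targ <- as.character(edges$target)
  if (anyNA(comp) || anyNA(targ)) stop("missing node id in edge list")
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else rep(1, nrow(edges))
  if (any(!is.finite(w)) || any(w <= 0)) stop("edge weights must be positive")

  both <- intersect(unique(comp), unique(targ))
  if (length(both) > 0L) {
    bad <- which(comp %in% both | targ %in% both)[1L]
    stop(sprintf(
      "bipartiteness violated: id(s) %s appear on both sides (first offending row %d)",
      paste(both, collapse = ", "), bad
    ))
  }

  key <- paste(comp, targ, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate edge(s) collapsed", sum(duplicated(key))))
    keep <- !duplicated(key)
    comp <- comp[keep]; targ <- targ[keep]; w <- w[keep]
  }
  net <- structure(
    list(
      components = sort(unique(comp)),
      targets = sort(unique(targ)),
      edges = data.frame(component = comp, target = targ, weight = w,
                         stringsAsFactors = FALSE)
    ),
    class = "ct_network"
  )
  if (allow_isolated) attr(net, "allow_isolated") <- TRUE
  net
}

#' Read a C-T network from an edge-list TSV
#'
#' The file must carry a header naming the `component` and `target` columns
#' (an optional `weight` column is honoured); if those names are absent the
#' first two columns are taken in that order.
#'
#' @param path path to a tab-separated edge list.
#' @return a [ct_network()] object.
#' @export
load_ct_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("network file not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("edge list needs at least two columns")
  if (!all(c("component", "target") %in% names(df))) {
    names(df)[1:2] <- c("component", "target")
  }
  ct_network(df)
}

#' Write a C-T network as a Cytoscape SIF file
#'
#' One `component interacts target` line per edge, sorted for stable diffs.
#'
#' @param net a `ct_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "ct_network"))
  e <- net$edges[order(net$edges$component, net$edges$target), , drop = FALSE]
  lines <- paste(e$component, "interacts", e$target, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a C-T network as an edge-list TSV
#'
#' @param net a `ct_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ct_network <- function(net, path) {
  stopifnot(inherits(net, "ct_network"))
  e <- net$edges[order(net$edges$component, net$edges$target), , drop = FALSE]
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Degree summary of a C-T network
#'
#' Mean degrees per side (edges divided by side size, the standard network
#' topology statistic for bipartite pharmacology networks) plus the top-k
#' highest-degree nodes on each side.
#'
#' @param net a `ct_network`.
#' @param k number of top nodes to report per side (default 3).
#' @return list with `mean_component_degree`, `mean_target_degree`,
#'   `top_components`, `top_targets` (named integer vectors).
#' @export
degree_summary <- function(net, k = 3L) {
  stopifnot(inherits(net, "ct_network"))
  ne <- nrow(net$edges)
  if (ne == 0L) stop("empty network")
  dc <- sort(table(net$edges$component), decreasing = TRUE)
  dt <- sort(table(net$edges$target), decreasing = TRUE)
  list(
    mean_component_degree = ne / length(net$components),
    mean_target_degree = ne / length(net$targets),
    top_components = utils::head(stats::setNames(as.integer(dc), names(dc)), k),
    top_targets = utils::head(stats::setNames(as.integer(dt), names(dt)), k)
  )
}

#' @export
print.ct_network <- function(x, ...) {
  cat(sprintf(
    "ct_network: %d components, %d targets, %d edges\n",
    length(x$components), length(x$targets), nrow(x$edges)
  ))
  invisible(x)
}

# Internal prefixed node ids: disjoint namespaces for walk-level code.
ct_node_ids <- function(net) {
  c(paste0("C:", net$components), paste0("T:", net$targets))
}

# Prefixed edge data.frame (from, to) for the random-walk layer.
ct_walk_edges <- function(net) {
  data.frame(
    from = paste0("C:", net$edges$component),
    to = paste0("T:", net$edges$target),
    stringsAsFactors = FALSE
  )
}

#' Restrict a C-T network to a node subset
#'
#' Keeps edges whose two endpoints are both retained. Used to scope
#' component ranking to the nodes of selected motifs.
#'
#' @param net a `ct_network`.
#' @param components,targets character vectors of ids to keep (default all).
#' @return a `ct_network`.
#' @export
subset_ct_network <- function(net, components = net$components,
                              targets = net$targets) {
  stopifnot(inherits(net, "ct_network"))
  e <- net$edges
  e <- e[e$component %in% components & e$target %in% targets, , drop = FALSE]
  if (nrow(e) == 0L) stop("subset has no edges")
  ct_network(e)
}
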