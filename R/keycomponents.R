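#' Rank components by target count within the motif scope
#'
#' Components are sorted in descending order of the number of targets they
#' hit inside the given network (typically the network restricted to the
#' FRM nodes, see [subset_ct_network()]). Ties are broken lexicographically
#' by component id — the ordering matters because the downstream
#' information gain is computed along it.
#'
#' @param net a `ct_network` (already restricted to the motif scope).
#' @return data.frame `component`, `T` ordered by descending `T` then id;
#'   attribute `target_sets` holds each component's target set in the same
#'   order.
#' @export
rank_by_target_count <- function(net) {
  stopifnot(inherits(net, "ct_network"))
  sets <- split(net$edges$target, net$edges$component)
  sets <- lapply(sets, unique)
  Tn <- vapply(sets, length, integer(1))
  ord <- order(-Tn, names(sets))
  out <- data.frame(component = names(sets)[ord], T = as.integer(Tn[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "target_sets") <- sets[ord]
  rownames(out) <- NULL
  out
}

#' Information gain of each component along an ordering
#'
#' For the n-th component in the ordering, the information gain is the
#' fraction of the total motif target set newly covered by it:
#' `dZ_n = |(TC_n \ union of earlier TC_i) intersect T_all| / |T_all|`.
#' The gains sum to 1 exactly when the components jointly cover `T_all`;
#' a component whose targets are all already covered gains 0.
#'
#' @param target_sets list of per-component target sets, in ranking order.
#' @param t_all character vector, the target set of all motifs.
#' @return numeric vector of gains aligned with `target_sets`.
#' @export
information_gain <- function(target_sets, t_all) {
  TA <- length(unique(t_all))
  if (TA == 0L) stop("empty motif target set")
  covered <- character(0)
  unname(vapply(target_sets, function(tc) {
    new <- setdiff(tc, covered)
    covered <<- union(covered, tc)
    length(intersect(new, t_all)) / TA
  }, numeric(1)))
}

#' Q scores from target counts and information gains
#'
#' Both vectors are min-max normalized and multiplied elementwise:
#' `Q = T_nor * dZ_nor`. When a vector is constant the min-max denominator
#' vanishes; the normalized value is then defined as 1 so a constant
#' dimension does not annihilate Q.
#'
#' @param components component ids, in ranking order.
#' @param T integer target counts.
#' @param dZ information gains from [information_gain()].
#' @return data.frame `component`, `T`, `dZ`, `T_nor`, `dZ_nor`, `Q`.
#' @export
q_scores <- function(components, T, dZ) {
  stopifnot(length(components) == length(T), length(T) == length(dZ))
  minmax <- function(x) {
    rng <- range(x)
    if (rng[2] - rng[1] <= 0) return(rep(1, length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
  }
  T_nor <- minmax(T)
  dZ_nor <- minmax(dZ)
  data.frame(component = components, T = as.integer(T), dZ = dZ,
             T_nor = T_nor, dZ_nor = dZ_nor, Q = T_nor * dZ_nor,
             stringsAsFactors = FALSE)
}

#' Select the key component group
#'
#' Keeps components with `Q` strictly above the threshold, ordered by `Q`
#' descending.
#'
#' @param scores data.frame from [q_scores()].
#' @param q_threshold strict lower bound on Q (default 0.01).
#' @return the filtered, reordered data.frame.
#' @export
select_key_components <- function(scores, q_threshold = 0.01) {
  out <- scores[scores$Q > q_threshold, , drop = FALSE]
  out <- out[order(-out$Q, out$component), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Score and rank components of a set of motifs
#'
#' Convenience wrapper: restricts the network to the motif nodes, ranks
#' components by within-scope target count, computes information gains
#' against the motif target union, and assembles Q scores.
#'
#' @param net the full `ct_network`.
#' @param frms an `sdfm_table` of selected motifs.
#' @param q_threshold threshold for [select_key_components()].
#' @return list with `scores` (all components) and `key` (the selected
#'   group).
#' @export
key_components <- function(net, frms, q_threshold = 0.01) {
  comp <- sdfm_components(frms)
  targ <- sdfm_targets(frms)
  sub <- subset_ct_network(net, components = comp, targets = targ)
  ranked <- rank_by_target_count(sub)
  dZ <- information_gain(attr(ranked, "target_sets"), targ)
  scores <- q_scores(ranked$component, ranked$T, dZ)
  list(scores = scores, key = select_key_components(scores, q_threshold))
}
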