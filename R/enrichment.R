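#' Hypergeometric over-representation p-value
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `K`
#' belong to the pathway: `P(X >= k)` under Hypergeometric(N, K, n), the
#' exact upper tail.
#'
#' @param k overlap count.
#' @param K pathway size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return the tail probability.
#' @export
hypergeom_p <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    stop("inconsistent hypergeometric counts")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values (monotone, capped at 1), in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Pathway over-representation analysis of a gene set
#'
#' One-sided hypergeometric test per pathway with at least one query gene,
#' BH-corrected across the tested pathways. The universe defaults to the
#' union of all collection genes and the query; query genes outside the
#' universe are dropped with a warning.
#'
#' @param genes character vector of query genes.
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param universe character vector of background genes, or `NULL` for the
#'   default.
#' @return data.frame with `pathway`, `k` (overlap), `K` (pathway size in
#'   universe), `n` (query size in universe), `N` (universe size), `p_raw`,
#'   `p_adj`, sorted by `p_raw`.
#' @export
enrich <- function(genes, collection, universe = NULL) {
  stopifnot(is.list(collection))
  if (is.null(universe)) {
    universe <- unique(c(unlist(collection, use.names = FALSE), genes))
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  genes <- unique(as.character(genes))
  outside <- setdiff(genes, universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside universe dropped",
                    length(outside)))
    genes <- setdiff(genes, outside)
  }
  if (length(genes) == 0L) {
    return(data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0)))
  }
  N <- length(universe)
  n <- length(genes)
  rows <- lapply(names(collection), function(id) {
    set <- intersect(collection[[id]], universe)
    k <- length(intersect(genes, set))
    if (k == 0L) return(NULL)
    data.frame(pathway = id, k = k, K = length(set), n = n, N = N,
               p_raw = hypergeom_p(k, length(set), n, N),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(pathway = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out <- out[order(out$p_raw, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter enrichment results by overlap count and pathway-name exclusions
#'
#' Retains pathways whose overlap count exceeds `min_count` (strict
#' greater-than) and whose name matches no exclusion term
#' (case-insensitive substring match). Used to discard small hits and
#' off-topic (e.g. unrelated-disease, viral, drug-resistance) pathways
#' before mechanism analysis.
#'
#' @param results data.frame from [enrich()].
#' @param min_count strict lower bound on `k` (default 12).
#' @param exclusion_terms character vector of name substrings to drop.
#' @param names optional named character vector mapping pathway id to
#'   display name; exclusions are matched against the name when given,
#'   else against the id.
#' @return the filtered data.frame.
#' @export
filter_pathways <- function(results, min_count = 12L,
                            exclusion_terms = character(0), names = NULL) {
  keep <- results$k > min_count
  label <- if (!is.null(names)) {
    ifelse(results$pathway %in% base::names(names),
           names[results$pathway], results$pathway)
  } else {
    results$pathway
  }
  for (term in exclusion_terms) {
    keep <- keep & !grepl(term, label, ignore.case = TRUE, fixed = FALSE)
  }
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

significant_pathways <- function(genes, collection, universe, alpha) {
  res <- enrich(genes, collection, universe)
  res$pathway[res$p_adj < alpha]
}

#' Pathway coverage of a motif gene set relative to the full network
#'
#' Fraction of the full C-T network's significantly enriched pathways that
#' are also significantly enriched for the motif genes:
#' `|sig(frm) intersect sig(ct)| / |sig(ct)|`, with significance at the
#' BH-adjusted level `alpha`. High coverage means the motifs preserve the
#' network's functional profile.
#'
#' @param frm_genes genes of the selected motifs.
#' @param ct_genes genes of the complete network.
#' @param collection gene-set collection.
#' @param universe background genes (`NULL` for the default of [enrich()]).
#' @param alpha adjusted-p significance level (default 0.05).
#' @return the coverage proportion in \[0, 1\].
#' @export
pathway_coverage <- function(frm_genes, ct_genes, collection,
                             universe = NULL, alpha = 0.05) {
  if (length(frm_genes) == 0L || length(ct_genes) == 0L) {
    stop("both gene sets must be non-empty")
  }
  sig_ct <- significant_pathways(ct_genes, collection, universe, alpha)
  if (length(sig_ct) == 0L) {
    stop("full network yields no significant pathway; coverage undefined")
  }
  sig_frm <- significant_pathways(frm_genes, collection, universe, alpha)
  length(intersect(sig_frm, sig_ct)) / length(sig_ct)
}

#' Proportion of reference pathways recovered by the motif genes
#'
#' The reference pathways are those significantly enriched in both the
#' network's target genes and the disease genes; the statistic is the
#' fraction of these also significant for the motif genes.
#'
#' @param frm_genes motif genes.
#' @param target_genes all network target genes.
#' @param disease_genes disease-associated genes.
#' @param collection gene-set collection.
#' @param universe background genes (`NULL` for the default).
#' @param alpha adjusted-p significance level (default 0.05).
#' @return the proportion in \[0, 1\].
#' @export
reference_pathway_proportion <- function(frm_genes, target_genes,
                                         disease_genes, collection,
                                         universe = NULL, alpha = 0.05) {
  reference <- intersect(
    significant_pathways(target_genes, collection, universe, alpha),
    significant_pathways(disease_genes, collection, universe, alpha)
  )
  if (length(reference) == 0L) stop("empty reference pathway set")
  sig_frm <- significant_pathways(frm_genes, collection, universe, alpha)
  length(intersect(sig_frm, reference)) / length(reference)
}

#' High-reliability disease gene sets
#'
#' Splits the disease table at its own means: one set holds the genes with
#' relevance score strictly above the mean relevance, the other the genes
#' with evidence count strictly above the mean count.
#'
#' @param disease disease-gene data.frame.
#' @return list with `by_relevance`, `by_evidence` (character vectors) and
#'   `thresholds` (the two means).
#' @export
high_reliable_sets <- function(disease) {
  validate_disease_table(disease)
  mr <- mean(disease$relevance_score)
  me <- mean(disease$n_evidence)
  list(
    by_relevance = disease$gene[disease$relevance_score > mr],
    by_evidence = disease$gene[disease$n_evidence > me],
    thresholds = c(relevance = mr, evidence = me)
  )
}

#' Disease-relevance summary of a motif gene set
#'
#' Mean relevance score and evidence count over the motif genes that are
#' annotated in the disease table, compared against each high-reliability
#' set with a two-sided Wilcoxon rank-sum test.
#'
#' @param frm_genes motif genes.
#' @param disease disease-gene data.frame.
#' @param high optional precomputed [high_reliable_sets()].
#' @return list with `n_annotated`, `mean_relevance`, `mean_evidence`,
#'   `table_mean_relevance`, `table_mean_evidence`, `p_vs_high_relevance`,
#'   `p_vs_high_evidence`.
#' @export
frm_disease_summary <- function(frm_genes, disease, high = NULL) {
  validate_disease_table(disease)
  if (is.null(high)) high <- high_reliable_sets(disease)
  annotated <- disease[disease$gene %in% frm_genes, , drop = FALSE]
  if (nrow(annotated) == 0L) stop("no motif gene annotated in disease table")
  wtest <- function(x, ref_genes, col) {
    ref <- disease[[col]][disease$gene %in% ref_genes]
    if (length(ref) == 0L || length(x) == 0L) return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, ref, exact = FALSE)$p.value)
  }
  list(
    n_annotated = nrow(annotated),
    mean_relevance = mean(annotated$relevance_score),
    mean_evidence = mean(annotated$n_evidence),
    table_mean_relevance = mean(disease$relevance_score),
    table_mean_evidence = mean(disease$n_evidence),
    p_vs_high_relevance = wtest(annotated$relevance_score,
                                high$by_relevance, "relevance_score"),
    p_vs_high_evidence = wtest(annotated$n_evidence,
                               high$by_evidence, "n_evidence")
  )
}
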