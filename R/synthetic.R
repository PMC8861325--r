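#' Specification of a planted-partition bipartite network
#'
#' The generator emulates a C-T network with known modular ground truth:
#' `n_modules` blocks, each holding `components_per_module` components and
#' `targets_per_module` targets; a component-target pair is connected with
#' probability `p_in` inside a block and `p_out` across blocks. Defaults
#' (3 blocks of 5 components + 10 targets, `p_in = 0.6`, `p_out = 0.05`)
#' give dense, clearly separated modules of the kind module detection is
#' expected to recover.
#'
#' @param n_modules number of planted modules (default 3).
#' @param components_per_module components per module (default 5).
#' @param targets_per_module targets per module (default 10).
#' @param p_in within-module edge probability (default 0.6).
#' @param p_out between-module edge probability (default 0.05).
#' @return a `planted_spec` list.
#' @export
planted_spec <- function(n_modules = 3L, components_per_module = 5L,
                         targets_per_module = 10L, p_in = 0.6,
                         p_out = 0.05) {
  if (n_modules < 1L || components_per_module < 1L ||
      targets_per_module < 1L) {
    stop("all counts must be at least 1")
  }
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  structure(list(n_modules = as.integer(n_modules),
                 components_per_module = as.integer(components_per_module),
                 targets_per_module = as.integer(targets_per_module),
                 p_in = p_in, p_out = p_out),
            class = "planted_spec")
}

#' Generate a bipartite network with planted modules
#'
#' Bernoulli edges per the [planted_spec()]; any node left isolated is
#' rewired with one random within-module edge so the network has no
#' degree-zero nodes. Byte-identical across runs for a fixed seed.
#'
#' @param spec a `planted_spec`.
#' @param seed integer RNG seed.
#' @return list with `network` (a `ct_network`) and `truth` (named integer
#'   vector over the prefixed walk node ids, the planted membership).
#' @export
generate_planted_network <- function(spec = planted_spec(), seed = 1L) {
  stopifnot(inherits(spec, "planted_spec"))
  set.seed(as.integer(seed))
  m <- spec$n_modules
  nc <- spec$components_per_module
  nt <- spec$targets_per_module
  comp_ids <- sprintf("cmp%02d_%02d", rep(seq_len(m), each = nc),
                      rep(seq_len(nc), m))
  targ_ids <- sprintf("tgt%02d_%02d", rep(seq_len(m), each = nt),
                      rep(seq_len(nt), m))
  comp_mod <- rep(seq_len(m), each = nc)
  targ_mod <- rep(seq_len(m), each = nt)

  pairs <- expand.grid(ci = seq_along(comp_ids), ti = seq_along(targ_ids))
  prob <- ifelse(comp_mod[pairs$ci] == targ_mod[pairs$ti],
                 spec$p_in, spec$p_out)
  keep <- stats::runif(nrow(pairs)) < prob
  edges <- data.frame(component = comp_ids[pairs$ci[keep]],
                      target = targ_ids[pairs$ti[keep]],
                      stringsAsFactors = FALSE)
  # rewire isolated nodes with one within-module edge
  for (i in seq_along(comp_ids)) {
    if (!comp_ids[i] %in% edges$component) {
      cand <- targ_ids[targ_mod == comp_mod[i]]
      edges <- rbind(edges, data.frame(
        component = comp_ids[i],
        target = cand[sample.int(length(cand), 1L)]))
    }
  }
  for (i in seq_along(targ_ids)) {
    if (!targ_ids[i] %in% edges$target) {
      cand <- comp_ids[comp_mod == targ_mod[i]]
      edges <- rbind(edges, data.frame(
        component = cand[sample.int(length(cand), 1L)],
        target = targ_ids[i]))
    }
  }
  if (nrow(edges) == 0L) stop("parameters produced an empty network")
  net <- ct_network(edges)
  truth <- c(stats::setNames(comp_mod, paste0("C:", comp_ids)),
             stats::setNames(targ_mod, paste0("T:", targ_ids)))
  list(network = net, truth = truth[order(names(truth))])
}

#' Generate a disease-gene score table with planted enrichment
#'
#' Targets in the `enriched_modules` draw their relevance score from a
#' log-normal shifted upward by `effect_size`; all other targets draw from
#' the baseline log-normal (meanlog 1, sdlog 0.6, matching the right-skewed
#' shape of database relevance scores). Evidence counts are over-dispersed
#' negative-binomial draws whose mean tracks the relevance score, so the
#' two annotations are positively correlated as in real exports.
#'
#' @param truth planted membership from [generate_planted_network()].
#' @param enriched_modules integer ids of the disease-enriched modules.
#' @param effect_size additive shift of the enriched relevance scores
#'   (default 8, a strong, clearly detectable disease signal).
#' @param seed integer RNG seed.
#' @return a disease-gene data.frame (`gene`, `relevance_score`,
#'   `n_evidence`).
#' @export
generate_disease_table <- function(truth, enriched_modules = integer(0),
                                   effect_size = 8, seed = 1L) {
  set.seed(as.integer(seed))
  if (length(enriched_modules) > 0L &&
      !all(enriched_modules %in% truth)) {
    stop("unknown module id in enriched_modules")
  }
  tnodes <- names(truth)[startsWith(names(truth), "T:")]
  genes <- sub("^T:", "", tnodes)
  mods <- truth[tnodes]
  enriched <- mods %in% enriched_modules
  relevance <- stats::rlnorm(length(genes), meanlog = 1, sdlog = 0.6)
  relevance[enriched] <- relevance[enriched] + effect_size
  n_evidence <- stats::rnbinom(length(genes), size = 2,
                               mu = pmax(0.5, relevance / 2))
  data.frame(gene = genes, relevance_score = relevance,
             n_evidence = as.numeric(n_evidence), stringsAsFactors = FALSE)
}

#' Generate a gene-set collection overlapping the planted modules
#'
#' One pathway is built around each planted module's target set, keeping a
#' fraction `overlap_frac` of its members and padding with random decoy
#' genes back to the original size; the remaining pathways are pure decoys
#' of random genes. With `overlap_frac = 1` a module pathway equals the
#' module's target set exactly.
#'
#' @param truth planted membership from [generate_planted_network()].
#' @param n_pathways total number of pathways (default 20).
#' @param overlap_frac fraction of module targets kept in each module
#'   pathway (default 0.9).
#' @param decoy_frac fraction of `n_pathways` that are pure decoys; module
#'   pathways are created first and never dropped (default 0.7).
#' @param n_decoy_genes size of the decoy gene pool (default 200).
#' @param seed integer RNG seed.
#' @return named list of gene sets (GMT-style).
#' @export
generate_genesets <- function(truth, n_pathways = 20L, overlap_frac = 0.9,
                              decoy_frac = 0.7, n_decoy_genes = 200L,
                              seed = 1L) {
  set.seed(as.integer(seed))
  tnodes <- names(truth)[startsWith(names(truth), "T:")]
  genes <- sub("^T:", "", tnodes)
  mods <- truth[tnodes]
  module_ids <- sort(unique(mods))
  decoy_pool <- sprintf("decoy%03d", seq_len(n_decoy_genes))
  sets <- list()
  for (mid in module_ids) {
    members <- genes[mods == mid]
    n_keep <- max(1L, round(overlap_frac * length(members)))
    kept <- sort(sample(members, n_keep))
    pad <- if (n_keep < length(members)) {
      sample(decoy_pool, length(members) - n_keep)
    } else {
      character(0)
    }
    sets[[sprintf("module_pathway_%02d", mid)]] <- c(kept, pad)
  }
  n_decoys <- max(0L, n_pathways - length(sets))
  for (d in seq_len(n_decoys)) {
    size <- sample(8:25, 1L)
    sets[[sprintf("decoy_pathway_%02d", d)]] <-
      sort(sample(decoy_pool, size))
  }
  sets
}

#' Generate a compound table with a known drug-like fraction
#'
#' Exactly `round(n * druglike_frac)` records satisfy every rule of the
#' default [screen_config()]; each remaining record violates at least one
#' randomly chosen rule, recorded in the `planted_violation` column.
#'
#' @param n number of compounds.
#' @param druglike_frac fraction passing the default screen (default 0.3,
#'   in the range typically seen when filtering natural-product libraries).
#' @param seed integer RNG seed.
#' @return compound data.frame (see [read_compound_table()]) plus the
#'   `planted_violation` bookkeeping column.
#' @export
generate_compound_table <- function(n, druglike_frac = 0.3, seed = 1L) {
  set.seed(as.integer(seed))
  if (n < 1L) stop("n must be at least 1")
  if (druglike_frac < 0 || druglike_frac > 1) stop("druglike_frac in [0,1]")
  n_pass <- round(n * druglike_frac)
  draw_pass <- function(k) {
    data.frame(
      mw = stats::runif(k, 150, 480),
      hbd = sample(0:5, k, replace = TRUE),
      hba = sample(0:10, k, replace = TRUE),
      logp = stats::runif(k, -2, 5),
      rotatable_bonds = sample(0:10, k, replace = TRUE),
      bioavailability = stats::runif(k, 0.3, 0.55),
      gi_absorption = rep("high", k),
      stringsAsFactors = FALSE
    )
  }
  df <- draw_pass(n)
  rules <- c("mw", "hbd", "hba", "logp", "rotatable_bonds",
             "bioavailability", "gi_absorption")
  violation <- rep("", n)
  if (n_pass < n) {
    for (i in (n_pass + 1L):n) {
      rule <- sample(rules, 1L)
      violation[i] <- rule
      switch(rule,
        mw = { df$mw[i] <- stats::runif(1, 500, 900) },
        hbd = { df$hbd[i] <- sample(6:12, 1L) },
        hba = { df$hba[i] <- sample(11:20, 1L) },
        logp = { df$logp[i] <- sample(c(stats::runif(1, -6, -2.1),
                                        stats::runif(1, 5.1, 9)), 1L) },
        rotatable_bonds = { df$rotatable_bonds[i] <- sample(11:20, 1L) },
        bioavailability = { df$bioavailability[i] <-
          sample(c(stats::runif(1, 0, 0.29), stats::runif(1, 0.56, 1)), 1L) },
        gi_absorption = { df$gi_absorption[i] <- "low" }
      )
    }
  }
  cbind(
    data.frame(compound_id = sprintf("CPD%04d", seq_len(n)),
               name = sprintf("compound-%04d", seq_len(n)),
               stringsAsFactors = FALSE),
    df,
    data.frame(planted_violation = violation, stringsAsFactors = FALSE)
  )
}

#' Generate the full synthetic input bundle
#'
#' One call producing every pipeline input with consistent ground truth: a
#' planted network, a disease table enriched in chosen modules, a gene-set
#' collection overlapping the planted modules, and a compound table.
#' Optionally writes all files (edge-list TSV, disease TSV, GMT, compound
#' TSV, ground-truth JSON) to a directory.
#'
#' @param preset `"small"` (3 modules of 5+10, the default stated world) or
#'   `"medium"` (5 modules of 8+16).
#' @param seed integer RNG seed; stage seeds are derived from it.
#' @param outdir optional directory to write the files into.
#' @return list with `network`, `truth`, `disease`, `genesets`,
#'   `compounds`, `enriched_modules`, and (when written) `paths`.
#' @export
simulate_bundle <- function(preset = c("small", "medium"), seed = 1L,
                            outdir = NULL) {
  preset <- match.arg(preset)
  spec <- switch(preset,
    small = planted_spec(),
    medium = planted_spec(n_modules = 5L, components_per_module = 8L,
                          targets_per_module = 16L)
  )
  seed <- as.integer(seed)
  pl <- generate_planted_network(spec, seed = stage_seed(seed, "network"))
  enriched <- 1L
  disease <- generate_disease_table(pl$truth, enriched_modules = enriched,
                                    seed = stage_seed(seed, "disease"))
  genesets <- generate_genesets(pl$truth, seed = stage_seed(seed, "genesets"))
  compounds <- generate_compound_table(20L, druglike_frac = 0.3,
                                       seed = stage_seed(seed, "compounds"))
  out <- list(network = pl$network, truth = pl$truth, disease = disease,
              genesets = genesets, compounds = compounds,
              enriched_modules = enriched)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      network = file.path(outdir, "network.tsv"),
      disease = file.path(outdir, "disease.tsv"),
      genesets = file.path(outdir, "genesets.gmt"),
      compounds = file.path(outdir, "compounds.tsv"),
      truth = file.path(outdir, "truth.json")
    )
    write_ct_network(pl$network, paths$network)
    utils::write.table(disease, paths$disease, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_gmt(genesets, paths$genesets)
    utils::write.table(compounds, paths$compounds, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(as.list(pl$truth), paths$truth, auto_unbox = TRUE)
    out$paths <- paths
  }
  out
}
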