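#' Default pipeline configuration
#'
#' Returns the resolved stage-by-stage parameter list. Unknown keys in
#' `overrides` are rejected so typos fail loudly.
#'
#' @param overrides named list of blocks/values to override.
#' @return nested list with blocks `inputs`, `screen`, `motifs`, `frms`,
#'   `enrich`, `keycomp`, plus `seed` and `outdir`.
#' @export
pipeline_config <- function(overrides = list()) {
  cfg <- list(
    seed = 1L,
    outdir = NULL,
    inputs = list(network = NULL, compounds = NULL, disease = NULL,
                  genesets = NULL),
    screen = list(enabled = TRUE),
    motifs = list(tau = 0.15, n_restarts = 8L, n_perm = 199L, alpha = 0.05),
    frms = list(strategy = "disease_count", capacity_frac = 0.5,
                ga_pop = 100L, ga_gens = 200L),
    enrich = list(alpha = 0.05, min_count = 12L,
                  exclusion_terms = character(0)),
    keycomp = list(q_threshold = 0.01)
  )
  merge_block <- function(base, over, path) {
    for (k in names(over)) {
      if (!k %in% names(base)) {
        stop(sprintf("unknown config key: %s%s", path, k))
      }
      if (is.list(base[[k]]) && is.list(over[[k]]) &&
          !is.null(names(base[[k]]))) {
        base[[k]] <- merge_block(base[[k]], over[[k]],
                                 paste0(path, k, "$"))
      } else {
        base[[k]] <- over[[k]]
      }
    }
    base
  }
  merge_block(cfg, overrides, "")
}

#' Run the full motif-discovery pipeline
#'
#' Stages in flowchart order: (1) drug-likeness screen of the compound
#' table; (2) network read + topology summary; (3) map-equation module
#' detection and permutation significance (SDFMs); (4) knapsack GA motif
#' selection (FRMs); (5) enrichment-based validation (pathway coverage,
#' disease-relevance summary); (6) Q-score key-component ranking. Any
#' stage failure is re-raised with the stage named. When `outdir` is set,
#' every JSON artifact embeds the resolved configuration and seed.
#'
#' @param config a list from [pipeline_config()], or a path to a JSON file
#'   holding the overrides.
#' @param bundle optional in-memory input bundle from [simulate_bundle()];
#'   when given, file inputs in the config are ignored.
#' @return list with `screen`, `network_summary`, `sdfm_table`, `sdfms`,
#'   `frms`, `knapsack`, `validation`, `keycomp`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), bundle = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    config <- pipeline_config(jsonlite::read_json(config, simplifyVector = TRUE))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  seed <- as.integer(config$seed)

  if (is.null(bundle)) {
    inputs <- config$inputs
    for (nm in c("network", "disease", "genesets")) {
      if (is.null(inputs[[nm]])) {
        stop(sprintf("pipeline stage 'inputs' failed: missing input path '%s'",
                     nm), call. = FALSE)
      }
      if (!file.exists(inputs[[nm]])) {
        stop(sprintf("pipeline stage 'inputs' failed: file not found: %s",
                     inputs[[nm]]), call. = FALSE)
      }
    }
    net <- stage("network", load_ct_network(inputs$network))
    disease <- stage("inputs", read_disease_table(inputs$disease))
    genesets <- stage("inputs", read_gmt(inputs$genesets))
    compounds <- if (!is.null(inputs$compounds)) {
      stage("inputs", read_compound_table(inputs$compounds))
    }
  } else {
    net <- bundle$network
    disease <- bundle$disease
    genesets <- bundle$genesets
    compounds <- bundle$compounds
  }

  screen_res <- NULL
  if (isTRUE(config$screen$enabled) && !is.null(compounds)) {
    screen_res <- stage("screen", screen_table(compounds))
  }

  net_summary <- stage("network", degree_summary(net))

  sdfm_all <- stage("motifs", {
    opt <- optimize_partition(net, tau = config$motifs$tau,
                              seed = stage_seed(seed, "motifs"),
                              n_restarts = config$motifs$n_restarts)
    module_significance(net, opt$membership, tau = config$motifs$tau,
                        n_perm = config$motifs$n_perm,
                        seed = stage_seed(seed, "significance"))
  })
  sdfms <- stage("motifs", select_sdfms(sdfm_all, config$motifs$alpha))
  if (nrow(sdfms) == 0L) {
    stop("pipeline stage 'motifs' failed: no significant module",
         call. = FALSE)
  }

  frm_res <- stage("frms", {
    inst <- build_instance(sdfms, disease,
                           strategy = config$frms$strategy,
                           capacity_frac = config$frms$capacity_frac)
    sol <- solve_ga(inst, ga_config(
      population_size = config$frms$ga_pop,
      generations = config$frms$ga_gens,
      seed = stage_seed(seed, "ga")))
    list(instance = inst, solution = sol,
         frms = frms_from_solution(sdfms, sol))
  })
  frms <- frm_res$frms

  validation <- stage("enrich", {
    frm_genes <- sdfm_targets(frms)
    ct_genes <- net$targets
    cov <- tryCatch(
      pathway_coverage(frm_genes, ct_genes, genesets,
                       alpha = config$enrich$alpha),
      error = function(e) NA_real_)
    summ <- tryCatch(frm_disease_summary(frm_genes, disease),
                     error = function(e) NULL)
    enr <- enrich(frm_genes, genesets)
    list(pathway_coverage = cov, disease_summary = summ,
         frm_enrichment = filter_pathways(
           enr, min_count = config$enrich$min_count,
           exclusion_terms = config$enrich$exclusion_terms),
         frm_enrichment_raw = enr)
  })

  keycomp <- stage("keycomp",
                   key_components(net, frms,
                                  q_threshold = config$keycomp$q_threshold))

  result <- list(screen = screen_res, network_summary = net_summary,
                 sdfm_table = sdfm_all, sdfms = sdfms, frms = frms,
                 knapsack = list(instance = frm_res$instance,
                                 solution = frm_res$solution),
                 validation = validation, keycomp = keycomp,
                 config = config)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    prov <- list(config = config, seed = seed)
    jsonlite::write_json(list(config = config),
                         file.path(config$outdir, "resolved_config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    write_result_json(list(
      sdfms = as.data.frame(sdfms),
      frms = as.data.frame(frms),
      members = attr(frms, "members"),
      knapsack = list(V = frm_res$solution$V, W = frm_res$solution$W,
                      capacity = frm_res$solution$capacity),
      validation = list(pathway_coverage = validation$pathway_coverage,
                        disease_summary = validation$disease_summary),
      key_components = keycomp$key
    ), file.path(config$outdir, "results.json"), provenance = prov)
    utils::write.table(keycomp$scores,
                       file.path(config$outdir, "component_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  result
}
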