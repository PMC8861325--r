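#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Empty sets are rejected; duplicate set ids are an
#' error.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stop("duplicate pathway ids in GMT")
  sets <- lapply(parts, function(p) {
    genes <- unique(p[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) stop(sprintf("empty gene set: %s", p[[1L]]))
    attr(genes, "description") <- if (length(p) >= 2L) p[[2L]] else ""
    genes
  })
  stats::setNames(sets, ids)
}

#' Write a gene-set collection to a GMT file
#'
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute each).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), length(names(sets)) == length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    desc <- attr(sets[[i]], "description")
    if (is.null(desc)) desc <- names(sets)[i]
    paste(c(names(sets)[i], desc, sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a disease-gene score table
#'
#' Tab-separated table with columns `gene`, `relevance_score`, `n_evidence`
#' in the style of GeneCards / DisGeNET exports: a per-gene disease
#' relevance score and a count of reporting evidence items.
#'
#' @param path path to a TSV file.
#' @return data.frame with one row per gene.
#' @export
read_disease_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("disease table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_disease_table(df)
}

validate_disease_table <- function(df) {
  need <- c("gene", "relevance_score", "n_evidence")
  if (!all(need %in% names(df))) {
    stop("disease table needs columns gene, relevance_score, n_evidence")
  }
  if (nrow(df) == 0L) stop("empty disease table")
  if (anyDuplicated(df$gene)) stop("duplicate gene in disease table")
  if (any(!is.finite(df$relevance_score)) || any(df$relevance_score < 0) ||
      any(!is.finite(df$n_evidence)) || any(df$n_evidence < 0)) {
    stop("disease scores must be finite and non-negative")
  }
  df
}

#' Read a compound property table
#'
#' Tab-separated table of molecular descriptors in the shape of a SwissADME
#' export: `compound_id`, `name`, `mw` (Da), `hbd`, `hba`, `logp`,
#' `rotatable_bonds`, `bioavailability` (score in \[0,1\]),
#' `gi_absorption` (`"high"`/`"low"`), optional `smiles`.
#'
#' @param path path to a TSV file.
#' @return data.frame of compound records.
#' @export
read_compound_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("compound table not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize a result object to JSON with provenance
#'
#' All pipeline artifacts are written through this helper so every output
#' embeds the parameters and seed that produced it.
#'
#' @param x a list-like result.
#' @param path output path.
#' @param provenance named list of resolved parameters (seed included).
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, provenance = list()) {
  payload <- list(result = x, provenance = provenance)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
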