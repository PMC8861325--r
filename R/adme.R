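#' Drug-likeness screen configuration
#'
#' Thresholds for the drug-likeness filter: Lipinski's Rule of Five
#' (molecular weight strictly below 500 Da; at most 5 hydrogen-bond donors;
#' at most 10 hydrogen-bond acceptors; logP between -2 and 5; at most 10
#' rotatable bonds) plus an oral bioavailability-score window of
#' \[0.30, 0.55\] and a high gastrointestinal-absorption requirement.
#' Boundary semantics follow the usual wording: "less than 500" is strict,
#' "does not exceed" and the two windows are inclusive.
#'
#' @param mw_max molecular weight upper bound in Da, exclusive (default 500).
#' @param hbd_max max H-bond donors, inclusive (default 5).
#' @param hba_max max H-bond acceptors, inclusive (default 10).
#' @param logp_min,logp_max inclusive logP window (default -2, 5).
#' @param rotb_max max rotatable bonds, inclusive (default 10).
#' @param bioavailability_min,bioavailability_max inclusive bioavailability
#'   score window (default 0.3, 0.55).
#' @param require_gi_high require `gi_absorption == "high"` (default TRUE).
#' @return a `screen_config` list.
#' @export
screen_config <- function(mw_max = 500, hbd_max = 5, hba_max = 10,
                          logp_min = -2, logp_max = 5, rotb_max = 10,
                          bioavailability_min = 0.3,
                          bioavailability_max = 0.55,
                          require_gi_high = TRUE) {
  cfg <- list(
    mw_max = mw_max, hbd_max = hbd_max, hba_max = hba_max,
    logp_min = logp_min, logp_max = logp_max, rotb_max = rotb_max,
    bioavailability_min = bioavailability_min,
    bioavailability_max = bioavailability_max,
    require_gi_high = isTRUE(require_gi_high)
  )
  if (cfg$logp_min > cfg$logp_max) stop("logp_min > logp_max")
  if (cfg$bioavailability_min > cfg$bioavailability_max) {
    stop("bioavailability_min > bioavailability_max")
  }
  structure(cfg, class = "screen_config")
}

.adme_fields <- c("mw", "hbd", "hba", "logp", "rotatable_bonds",
                  "bioavailability", "gi_absorption")

#' Evaluate one compound against the drug-likeness screen
#'
#' A compound passes only if it violates no rule (strict conjunction; the
#' customary "at most one Lipinski violation" relaxation is not applied).
#'
#' @param compound list or one-row data.frame with fields `mw`, `hbd`,
#'   `hba`, `logp`, `rotatable_bonds`, `bioavailability`, `gi_absorption`.
#' @param cfg a [screen_config()].
#' @return list with `pass` (logical) and `violated` (character vector of
#'   rule ids among `mw`, `hbd`, `hba`, `logp`, `rotatable_bonds`,
#'   `bioavailability`, `gi_absorption`).
#' @export
evaluate_compound <- function(compound, cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  c_ <- as.list(compound)
  for (f in .adme_fields) {
    if (is.null(c_[[f]]) || length(c_[[f]]) != 1L || is.na(c_[[f]])) {
      stop(sprintf("missing descriptor: %s", f))
    }
  }
  violated <- character(0)
  if (!(c_$mw < cfg$mw_max)) violated <- c(violated, "mw")
  if (!(c_$hbd <= cfg$hbd_max)) violated <- c(violated, "hbd")
  if (!(c_$hba <= cfg$hba_max)) violated <- c(violated, "hba")
  if (!(c_$logp >= cfg$logp_min && c_$logp <= cfg$logp_max)) {
    violated <- c(violated, "logp")
  }
  if (!(c_$rotatable_bonds <= cfg$rotb_max)) {
    violated <- c(violated, "rotatable_bonds")
  }
  if (!(c_$bioavailability >= cfg$bioavailability_min &&
        c_$bioavailability <= cfg$bioavailability_max)) {
    violated <- c(violated, "bioavailability")
  }
  if (cfg$require_gi_high && !identical(tolower(as.character(c_$gi_absorption)), "high")) {
    violated <- c(violated, "gi_absorption")
  }
  list(pass = length(violated) == 0L, violated = violated)
}

#' Screen a compound table for drug-likeness
#'
#' @param compounds data.frame of compound records (see
#'   [read_compound_table()]).
#' @param cfg a [screen_config()].
#' @return list with `passed` (subset of `compounds`) and `report`
#'   (data.frame `compound_id`, `pass`, `violated` with rule ids joined by
#'   `","`); every input row appears in the report exactly once.
#' @export
screen_table <- function(compounds, cfg = screen_config()) {
  stopifnot(is.data.frame(compounds))
  if (nrow(compounds) == 0L) stop("empty compound table")
  res <- lapply(seq_len(nrow(compounds)), function(i) {
    evaluate_compound(compounds[i, , drop = FALSE], cfg)
  })
  pass <- vapply(res, `[[`, logical(1), "pass")
  report <- data.frame(
    compound_id = as.character(compounds$compound_id),
    pass = pass,
    violated = vapply(res, function(r) paste(r$violated, collapse = ","),
                      character(1)),
    stringsAsFactors = FALSE
  )
  list(passed = compounds[pass, , drop = FALSE], report = report)
}
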