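#' Computational success criteria
#'
#' Threshold set for classifying a design as computationally
#' successful. The lax tier requires `pLDDT > 70` and `scRMSD < 2` A;
#' the strict tier (binder designs) requires `pLDDT > 80`,
#' `scRMSD < 1` A and `ipAE < 10` A. All inequalities are strict:
#' boundary values fail.
#'
#' @param plddt_lax,scrmsd_lax Lax-tier thresholds.
#' @param plddt_strict,scrmsd_strict,ipae_strict Strict-tier thresholds.
#' @return Object of class `success_criteria`.
#' @export
success_criteria <- function(plddt_lax = 70, scrmsd_lax = 2,
                             plddt_strict = 80, scrmsd_strict = 1,
                             ipae_strict = 10) {
  structure(list(plddt_lax = plddt_lax, scrmsd_lax = scrmsd_lax,
                 plddt_strict = plddt_strict, scrmsd_strict = scrmsd_strict,
                 ipae_strict = ipae_strict),
            class = "success_criteria")
}

#' Self-consistency benchmark of a designed sequence
#'
#' Re-predicts the (re)designed sequence with each configured oracle (4
#' recycling steps by default, the validation-stage setting; binder
#' tasks supply the target template and initialise recycling with the
#' designed complex) and measures agreement with the design's raw
#' structure: scRMSD (CA Kabsch RMSD), scTM, mean pLDDT, mean pAE,
#' interface pAE for multi-chain designs, and pTM.
#'
#' @param raw The designed raw [pd_structure()].
#' @param sequence The sequence to re-predict ([chained_seq()]).
#' @param oracles Named list of oracles; one record row per oracle.
#' @param template Optional [pd_template()] pinned to `target_chain`.
#' @param target_chain Chain id of the fixed target, if any.
#' @param recycles Recycling steps (default 4).
#' @param design_id Identifier carried into the record.
#' @return data.frame (`benchmark_record`) with one row per oracle:
#'   `design_id`, `oracle`, `scrmsd`, `sctm`, `plddt`, `pae`, `ipae`
#'   (NA for monomers), `ptm`. Oracle failures are recorded per row
#'   (`error` column), not raised.
#' @export
self_consistency <- function(raw, sequence, oracles, template = NULL,
                             target_chain = NULL, recycles = 4L,
                             design_id = "design") {
  stopifnot(inherits(raw, "pd_structure"), inherits(sequence, "chained_seq"))
  if (n_residues(raw) != seq_length(sequence))
    pd_stop("structural_mismatch", "sequence and raw structure lengths differ")
  if (!length(oracles)) pd_stop("invalid_config", "need at least one oracle")
  if (is.null(names(oracles))) names(oracles) <- paste0("oracle", seq_along(oracles))
  rows <- lapply(names(oracles), function(nm) {
    res <- tryCatch({
      tpl <- if (!is.null(template))
        stats::setNames(list(template), target_chain)
      req <- oracle_request(sequence, templates = tpl,
                            recycle_count = recycles, init_structure = raw)
      pred <- predict_structure(oracles[[nm]], req)
      multi <- length(sequence$chains) > 1L
      ipae <- NA_real_
      if (multi) {
        x <- sequence$chain_ids[1]
        others <- setdiff(sequence$chain_ids, x)
        ipae <- (1 - ipae_term(pred, x, others)) * pred$pae_max
      }
      data.frame(design_id = design_id, oracle = nm,
                 scrmsd = kabsch_rmsd(raw, pred$structure),
                 sctm = tm_score(raw, pred$structure),
                 plddt = mean(pred$plddt), pae = mean(pred$pae),
                 ipae = ipae, ptm = pred$ptm, error = NA_character_,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(design_id = design_id, oracle = nm, scrmsd = NA_real_,
                 sctm = NA_real_, plddt = NA_real_, pae = NA_real_,
                 ipae = NA_real_, ptm = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  rec <- do.call(rbind, rows)
  class(rec) <- c("benchmark_record", class(rec))
  rec
}

#' Classify benchmark records against success criteria
#'
#' Applies the threshold logic with strict inequalities exactly:
#' `lax = pLDDT > 70 & scRMSD < 2`;
#' `strict = pLDDT > 80 & scRMSD < 1 & ipAE < 10`. Requesting the
#' strict tier on a record without an ipAE value is an error, because
#' the tier is undefined for monomer records.
#'
#' @param rec A `benchmark_record` data.frame (or any data.frame with
#'   `plddt`, `scrmsd` and optionally `ipae` columns).
#' @param crit A [success_criteria()].
#' @param tiers Which flags to compute (default both where possible).
#' @return `rec` with logical columns `lax` (and `strict` if requested).
#' @export
classify_success <- function(rec, crit = success_criteria(),
                             tiers = c("lax", "strict")) {
  stopifnot(is.data.frame(rec))
  if ("lax" %in% tiers)
    rec$lax <- rec$plddt > crit$plddt_lax & rec$scrmsd < crit$scrmsd_lax
  if ("strict" %in% tiers) {
    if (!("ipae" %in% names(rec)) || anyNA(rec$ipae))
      pd_stop("incomplete_record", "strict tier requires ipAE on every record")
    rec$strict <- rec$plddt > crit$plddt_strict &
      rec$scrmsd < crit$scrmsd_strict & rec$ipae < crit$ipae_strict
  }
  rec
}

#' Select the best redesigned sequence for a design
#'
#' First applies all success thresholds for the requested tier, then
#' sorts the passing records by scRMSD and returns the minimum;
#' `NULL` if nothing passes (failure reasons attached). Ties in scRMSD
#' are broken by `design_id` so the choice does not depend on record
#' order.
#'
#' @param records Benchmark records for one design's redesigns.
#' @param crit A [success_criteria()].
#' @param tier `"lax"` (default) or `"strict"`.
#' @return The chosen record row, or a zero-row record when nothing
#'   passes, with per-record failure reasons in the `reasons` attribute.
#' @export
select_best <- function(records, crit = success_criteria(), tier = "lax") {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  flagged <- classify_success(records, crit, tiers = tier)
  pass <- flagged[!is.na(flagged[[tier]]) & flagged[[tier]], , drop = FALSE]
  if (!nrow(pass)) {
    reasons <- vapply(seq_len(nrow(flagged)), function(i) {
      r <- flagged[i, ]
      why <- c(if (!is.na(r$plddt) && r$plddt <= crit[[paste0("plddt_", tier)]])
                 "pLDDT below threshold",
               if (!is.na(r$scrmsd) && r$scrmsd >= crit[[paste0("scrmsd_", tier)]])
                 "scRMSD above threshold",
               if (tier == "strict" && !is.na(r$ipae) && r$ipae >= crit$ipae_strict)
                 "ipAE above threshold",
               if (!is.null(r$error) && !is.na(r$error)) r$error)
      paste(why, collapse = "; ")
    }, "")
    out <- flagged[0, , drop = FALSE]
    attr(out, "reasons") <- stats::setNames(reasons, flagged$design_id)
    return(out)
  }
  pass[order(pass$scrmsd, pass$design_id)[1], , drop = FALSE]
}

#' Candidate filter cascade
#'
#' The selection gates applied to each candidate after redesign, in
#' fixed order: drop if mean log-likelihood < -0.1 nats/residue; drop
#' if `pLDDT * pTM < 0.5` (pLDDT on the \[0, 1\] scale -- on the 0-100
#' scale the threshold would be vacuous); drop if a solubility score is
#' supplied and is below 1. The solubility gate is an external hook:
#' when no score is supplied it is recorded as `"not evaluated"` and
#' skipped.
#'
#' @param loglik Mean log-likelihood (nats/residue).
#' @param plddt Mean pLDDT on \[0, 1\].
#' @param ptm pTM in \[0, 1\].
#' @param solubility Optional solubility score (higher is better).
#' @param loglik_min,conf_min,solubility_min Gate thresholds (defaults
#'   -0.1, 0.5, 1).
#' @return List with `keep` (logical), `reasons` (character vector of
#'   failed gates) and `gates` (data.frame of gate/value/threshold/status).
#' @export
filter_cascade <- function(loglik, plddt, ptm, solubility = NULL,
                           loglik_min = -0.1, conf_min = 0.5,
                           solubility_min = 1) {
  gates <- data.frame(
    gate = c("likelihood", "confidence", "solubility"),
    value = c(loglik, plddt * ptm,
              if (is.null(solubility)) NA_real_ else solubility),
    threshold = c(loglik_min, conf_min, solubility_min),
    status = NA_character_, stringsAsFactors = FALSE)
  gates$status[1] <- if (loglik < loglik_min) "fail" else "pass"
  gates$status[2] <- if (plddt * ptm < conf_min) "fail" else "pass"
  gates$status[3] <- if (is.null(solubility)) "not evaluated"
                     else if (solubility < solubility_min) "fail" else "pass"
  reasons <- gates$gate[gates$status == "fail"]
  list(keep = !length(reasons), reasons = reasons, gates = gates)
}
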