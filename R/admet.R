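#' Topological polar surface area and logP descriptors
#'
#' `compute_tpsa()` returns the Ertl fragment-contribution topological
#' polar surface area in Angstrom^2; `compute_logp()` returns an
#' atom-contribution octanol/water logP. Both are computed from the
#' connection table only (no 3D), so two SMILES encodings of the same
#' molecule give identical values.
#'
#' @param smiles character vector of SMILES (or a `molecule_library`
#'   data.frame, whose `smiles` column is used).
#' @return numeric vector of descriptor values.
#' @examples
#' compute_tpsa("CCO")       # 20.23 (single hydroxyl)
#' compute_tpsa("c1ccncc1")  # 12.89 (aromatic N)
#' @export
compute_tpsa <- function(smiles) {
  descriptors_ob(smiles)$TPSA
}

#' @rdname compute_tpsa
#' @export
compute_logp <- function(smiles) {
  descriptors_ob(smiles)$logP
}

descriptors_ob <- function(smiles) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  ok <- is_valid_smiles(smiles)
  if (any(!ok))
    stopf("invalid structure(s): %s",
          paste(utils::head(smiles[!ok], 5L), collapse = ", "))
  sdf <- suppressWarnings(
    ChemmineR::smiles2sdf(stats::setNames(smiles,
                                          paste0("m", seq_along(smiles)))))
  ChemmineR::propOB(sdf)
}

#' Passive blood-brain-barrier permeation rule
#'
#' Physicochemical classification of passive BBB permeation: a compound is
#' classed `penetrant` iff it has moderate polarity, tPSA < 79 Angstrom^2,
#' and moderate lipophilicity, 0.4 < logP < 6.0 (all inequalities strict);
#' otherwise `non_penetrant`.
#'
#' @param tpsa topological polar surface area, Angstrom^2.
#' @param logp octanol/water logP.
#' @return character vector, `"penetrant"` or `"non_penetrant"`.
#' @examples
#' passive_bbb_rule(50, 2.0)  # penetrant
#' passive_bbb_rule(79, 2.0)  # non_penetrant (boundary is strict)
#' @export
passive_bbb_rule <- function(tpsa, logp) {
  stopifnot(is.numeric(tpsa), is.numeric(logp))
  ifelse(tpsa < 79 & logp > 0.4 & logp < 6.0, "penetrant", "non_penetrant")
}

bbb_levels <- c("penetrant", "weak_penetrant", "non_penetrant")

#' Consensus BBB classification across prediction models
#'
#' Combines per-model BBB labels into one call: `weak_penetrant` labels
#' are first demoted to `non_penetrant`, then the compound is classed
#' `penetrant` iff \emph{any} model labels it penetrant. The rule is
#' order-independent and idempotent under label duplication.
#'
#' @param labels character vector of labels from the closed vocabulary
#'   `penetrant` / `weak_penetrant` / `non_penetrant` (one compound), or a
#'   data.frame with columns `compound_id`, `label` (many compounds).
#' @return a single label, or (for a data.frame) a data.frame with one
#'   consensus label per compound.
#' @examples
#' consensus_bbb(c("non_penetrant", "penetrant"))       # penetrant
#' consensus_bbb(c("non_penetrant", "weak_penetrant"))  # non_penetrant
#' @export
consensus_bbb <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(all(c("compound_id", "label") %in% names(labels)))
    ids <- unique(labels$compound_id)
    out <- vapply(ids, function(id)
      consensus_bbb(labels$label[labels$compound_id == id]), character(1))
    return(data.frame(compound_id = ids, consensus = unname(out),
                      stringsAsFactors = FALSE))
  }
  if (!length(labels)) stopf("consensus_bbb needs at least one label")
  bad <- setdiff(labels, bbb_levels)
  if (length(bad))
    stopf("unknown BBB label(s): %s", paste(unique(bad), collapse = ", "))
  mapped <- ifelse(labels == "weak_penetrant", "non_penetrant", labels)
  if (any(mapped == "penetrant")) "penetrant" else "non_penetrant"
}

#' Derek-style likelihood scale for toxicity predictions
#'
#' The ordered likelihood vocabulary used by knowledge-base toxicity
#' predictions, from highest to lowest: certain, probable, plausible,
#' equivocal, doubted, improbable, impossible.
#'
#' @return character vector of the seven levels in decreasing order.
#' @export
toxicity_likelihood_levels <- function() {
  c("certain", "probable", "plausible", "equivocal", "doubted",
    "improbable", "impossible")
}

#' Toxicity gate over ingested structural-alert predictions
#'
#' Flags compounds having any toxicity endpoint predicted at or above the
#' likelihood threshold on the ordered scale (default `plausible`, i.e.
#' the weight of evidence supports the proposition). The default action is
#' to annotate only — flagged compounds stay in the hit list with their
#' alerts attached, leaving the removal decision to the analyst; with
#' `action = "remove"` they are filtered out instead.
#'
#' @param records a `molecule_library` data.frame (or any data.frame with
#'   `compound_id`).
#' @param annotations data.frame with columns `compound_id`, `endpoint`,
#'   `likelihood` (values from [toxicity_likelihood_levels()]).
#' @param likelihood_threshold threshold level; prediction at this level
#'   or stronger raises a flag.
#' @param action `"annotate"` (default) or `"remove"`.
#' @return list with `kept` (records, with a `tox_flags` column giving
#'   `endpoint:likelihood` pairs or `""`), `removed` (data.frame:
#'   compound_id, reason; empty unless `action = "remove"`), and `flagged`
#'   (compound ids that raised a flag).
#' @export
toxicity_gate <- function(records, annotations,
                          likelihood_threshold = "plausible",
                          action = c("annotate", "remove")) {
  action <- match.arg(action)
  levels <- toxicity_likelihood_levels()
  stopifnot(likelihood_threshold %in% levels)
  if (is.null(annotations) || !nrow(annotations)) {
    annotations <- data.frame(compound_id = character(),
                              endpoint = character(),
                              likelihood = character(),
                              stringsAsFactors = FALSE)
  }
  bad <- setdiff(annotations$likelihood, levels)
  if (length(bad))
    stopf("unknown likelihood level(s): %s", paste(unique(bad), collapse = ", "))
  thr_rank <- match(likelihood_threshold, levels)
  hot <- annotations[match(annotations$likelihood, levels) <= thr_rank, ,
                     drop = FALSE]
  flags <- vapply(records$compound_id, function(id) {
    h <- hot[hot$compound_id == id, , drop = FALSE]
    if (!nrow(h)) "" else paste(h$endpoint, h$likelihood, sep = ":",
                                collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  out <- records
  out$tox_flags <- flags
  flagged <- records$compound_id[nzchar(flags)]
  if (action == "remove") {
    removed <- data.frame(compound_id = flagged,
                          reason = flags[nzchar(flags)],
                          stringsAsFactors = FALSE)
    out <- out[!nzchar(flags), , drop = FALSE]
  } else {
    removed <- data.frame(compound_id = character(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  list(kept = out, removed = removed, flagged = flagged)
}
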