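#' Bundled reference hit set: 16 multi-target screening hits
#'
#' The packaged reference dataset of 16 triple-active hits from a virtual
#' screening campaign against AChE, HDAC2 and MAO-B: vendor name, SMILES
#' (protonation states as screened), the predicted Ki (nM, geometric mean
#' of a predicted affinity range) against each target, and the reported Ki
#' multiplication product. These compounds all satisfy the affinity gate
#' (each Ki < 5000 nM, product < 1e8 nM^3) and are used throughout the test
#' suite and examples.
#'
#' @return list with components `records` (a `molecule_library` of 16
#'   compounds; `compound_id` is the vendor name), `affinities` (long
#'   data.frame: compound_id, target, ki_nM), and `table` (the raw wide
#'   table, one row per compound, including `product_reported_nM3`).
#' @examples
#' fx <- hit_fixture()
#' nrow(fx$records)  # 16
#' @export
hit_fixture <- function() {
  path <- system.file("extdata", "hit_table.csv", package = "mtscreen",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  records <- as_molecule_library(tab$name, tab$smiles, name = tab$name)
  aff <- data.frame(
    compound_id = rep(tab$name, times = 3),
    target = rep(c("AChE", "HDAC2", "MAOB"), each = nrow(tab)),
    ki_nM = c(tab$ki_ache_nM, tab$ki_hdac2_nM, tab$ki_maob_nM),
    stringsAsFactors = FALSE)
  list(records = records, affinities = aff, table = tab)
}

#' Bundled reference BBB / toxicity label set for the four final hits
#'
#' Per-hit blood-brain-barrier labels from two external prediction models
#' (a physicochemical tPSA/logP classifier and a transport-based
#' classifier) plus structural-alert toxicity predictions, for the four
#' hits surviving the pharmacophore stage. These are ingested labels, not
#' recomputed predictions.
#'
#' @return data.frame with 4 rows and columns `name`, `swiss_label`,
#'   `percepta_label`, `consensus_reported`, `derek_flags` (semicolon-
#'   separated `endpoint:likelihood` pairs, empty when no alert fired).
#' @seealso [bbb_fixture_labels()], [bbb_fixture_toxicity()] for the same
#'   data reshaped for [consensus_bbb()] and [toxicity_gate()].
#' @export
bbb_fixture <- function() {
  path <- system.file("extdata", "bbb_table.csv", package = "mtscreen",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  df$derek_flags[is.na(df$derek_flags)] <- ""
  df
}

#' @describeIn bbb_fixture the BBB labels in long form
#'   (compound_id, model, label), ready for [consensus_bbb()].
#' @export
bbb_fixture_labels <- function() {
  df <- bbb_fixture()
  data.frame(
    compound_id = rep(df$name, times = 2),
    model = rep(c("swissadme", "percepta"), each = nrow(df)),
    label = c(df$swiss_label, df$percepta_label),
    stringsAsFactors = FALSE)
}

#' @describeIn bbb_fixture the toxicity annotations in long form
#'   (compound_id, endpoint, likelihood), ready for [toxicity_gate()].
#' @export
bbb_fixture_toxicity <- function() {
  df <- bbb_fixture()
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    fl <- df$derek_flags[i]
    if (!nzchar(fl)) return(NULL)
    parts <- strsplit(strsplit(fl, ";")[[1]], ":")
    data.frame(compound_id = df$name[i],
               endpoint = vapply(parts, `[`, "", 1L),
               likelihood = vapply(parts, `[`, "", 2L),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(compound_id = character(), endpoint = character(),
                      likelihood = character(), stringsAsFactors = FALSE)
  out
}

#' Reference-ligand docking score ranges
#'
#' The bundled re-docking and cross-docking score ranges (kcal/mol, more
#' negative is better) of the three co-crystallized reference ligands
#' (donepezil for AChE, a benzamide derivative for HDAC2, safinamide for
#' MAO-B) under the rigid and flexible docking protocols. Each range spans
#' the scores of the best 10 retained poses. Rows with `is_reference ==
#' TRUE` are re-docking (ligand docked into its own receptor); the rest are
#' cross-docking.
#'
#' @return data.frame with columns `target`, `protocol`, `ligand`,
#'   `score_low`, `score_high`, `is_reference`.
#' @seealso [reference_thresholds()]
#' @export
reference_score_ranges <- function() {
  path <- system.file("extdata", "reference_scores.csv",
                      package = "mtscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Per-target selection thresholds from the reference re-docking scores
#'
#' The selection threshold for each target is the best (most negative)
#' re-docking score of its own co-crystallized ligand; a screened compound
#' passes only if it scores strictly better on every target
#' (see [triple_activity_filter()]).
#'
#' @param protocol `"rigid"` or `"flexible"`.
#' @return named numeric vector of thresholds (kcal/mol), one per target.
#' @examples
#' reference_thresholds("flexible")  # AChE -8.52, HDAC2 -7.68, MAOB -8.34
#' @export
reference_thresholds <- function(protocol = c("rigid", "flexible")) {
  protocol <- match.arg(protocol)
  df <- reference_score_ranges()
  df <- df[df$protocol == protocol & df$is_reference, ]
  stats::setNames(df$score_low, df$target)
}
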