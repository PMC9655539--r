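#' Reference re-docking profile
#'
#' A set of docking pose scores (kcal/mol, more negative is better) for a
#' reference ligand re-docked into one target under one protocol. Its best
#' pose score defines the selection threshold for that target.
#'
#' @param target target name.
#' @param protocol `"rigid"` or `"flexible"`.
#' @param pose_scores numeric vector of pose scores; must be non-empty and
#'   finite.
#' @return object of class `reference_profile`.
#' @export
reference_profile <- function(target, protocol = c("rigid", "flexible"),
                              pose_scores) {
  protocol <- match.arg(protocol)
  if (!length(pose_scores)) stopf("empty reference profile for %s", target)
  if (!all(is.finite(pose_scores)))
    stopf("non-finite pose score in reference profile for %s", target)
  structure(list(target = target, protocol = protocol,
                 pose_scores = as.numeric(pose_scores)),
            class = "reference_profile")
}

#' Derive a selection threshold from a reference profile
#'
#' The threshold is the best (minimum, i.e. most negative) pose score of
#' the re-docked reference ligand. A screened compound later passes the
#' gate only if its score is strictly below this value — it must out-score
#' the reference on its own receptor.
#'
#' @param profile a [reference_profile()], or a bare numeric vector of pose
#'   scores.
#' @return the threshold score (scalar).
#' @examples
#' derive_threshold(c(-8.52, -7.1, -6.29))  # -8.52
#' @export
derive_threshold <- function(profile) {
  scores <- if (inherits(profile, "reference_profile")) profile$pose_scores
            else profile
  if (!length(scores)) stopf("empty reference profile")
  if (!all(is.finite(scores))) stopf("non-finite score in reference profile")
  min(scores)
}

#' Closed-interval score range and overlap test
#'
#' Score ranges are treated as closed intervals: two ranges overlap iff
#' `a$low <= b$high && b$low <= a$high`, so ranges that merely touch at an
#' endpoint count as overlapping. (Printed score ranges are rounded to two
#' decimals; an open-interval rule would be numerically fragile.) Overlap
#' of a ligand's cross-docking range with the receptor's own re-docking
#' range indicates binding-site compatibility.
#'
#' @param low,high interval bounds, `low <= high` (scores in kcal/mol, so
#'   `low` is the better score).
#' @return `score_interval`: a list with `low` and `high`.
#' @export
score_interval <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L)
  if (low > high) stopf("invalid interval: low (%g) > high (%g)", low, high)
  structure(list(low = low, high = high), class = "score_interval")
}

#' @rdname score_interval
#' @param a,b `score_interval` objects (or lists with `low`/`high`).
#' @return `ranges_overlap()`: logical.
#' @examples
#' ranges_overlap(score_interval(-11.72, -10.42),
#'                score_interval(-13.01, -11.30))  # TRUE
#' @export
ranges_overlap <- function(a, b) {
  a$low <= b$high && b$low <= a$high
}

#' Triple-activity docking-score filter
#'
#' Retains only compounds whose docking score is strictly better (more
#' negative) than the per-target threshold on \emph{every} target — i.e.
#' compounds predicted to out-score the re-docked reference ligand in all
#' three binding sites simultaneously. Compounds missing a score for any
#' required target are excluded and logged (never silently dropped).
#'
#' @param scores long data.frame with columns `compound_id`, `target` and
#'   the score column named by `score_col` (default picks
#'   `rigid_score`/`flexible_score` by `protocol`).
#' @param thresholds named numeric vector, one threshold per target; the
#'   names define the required target set.
#' @param protocol `"rigid"` or `"flexible"`; ignored when `score_col` is
#'   given.
#' @param score_col optional explicit score column name.
#' @return list with `kept` (surviving compound ids, input order
#'   preserved) and `removed` (data.frame: compound_id, reason,
#'   failed_targets).
#' @examples
#' sc <- data.frame(compound_id = rep("A", 3),
#'                  target = c("AChE", "HDAC2", "MAOB"),
#'                  rigid_score = c(-20, -20, -20))
#' triple_activity_filter(sc, c(AChE = -8.52, HDAC2 = -7.68, MAOB = -8.34),
#'                        protocol = "rigid")$kept  # "A"
#' @export
triple_activity_filter <- function(scores, thresholds,
                                   protocol = c("rigid", "flexible"),
                                   score_col = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(score_col)) score_col <- paste0(protocol, "_score")
  need <- c("compound_id", "target", score_col)
  miss <- setdiff(need, names(scores))
  if (length(miss))
    stopf("score table lacks column(s): %s", paste(miss, collapse = ", "))
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds))))
    stopf("thresholds must be named by target")
  targets <- names(thresholds)

  ids <- unique(scores$compound_id)
  sub <- scores[scores$target %in% targets &
                  is.finite(scores[[score_col]]), , drop = FALSE]
  # score matrix: compounds x targets (first score per pair wins)
  key <- paste(sub$compound_id, sub$target, sep = "\r")
  sub <- sub[!duplicated(key), , drop = FALSE]
  smat <- matrix(NA_real_, nrow = length(ids), ncol = length(targets),
                 dimnames = list(ids, targets))
  smat[cbind(match(sub$compound_id, ids), match(sub$target, targets))] <-
    sub[[score_col]]

  below <- sweep(smat, 2, thresholds[targets], `<`)       # strict inequality
  failed_mat <- is.na(smat) | !below
  missing_any <- rowSums(is.na(smat)) > 0L
  pass <- rowSums(failed_mat) == 0L

  removed_idx <- which(!pass)
  removed <- data.frame(
    compound_id = ids[removed_idx],
    reason = ifelse(missing_any[removed_idx], "missing_target_score",
                    "score_above_threshold"),
    failed_targets = vapply(removed_idx, function(i)
      paste(targets[failed_mat[i, ]], collapse = ";"), character(1)),
    stringsAsFactors = FALSE)
  list(kept = ids[pass], removed = removed)
}
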