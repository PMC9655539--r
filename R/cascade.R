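#' Cascade configuration
#'
#' Declarative configuration for [run_cascade()]. Defaults encode the
#' standard triage parameters: per-target docking-score thresholds derived
#' from the bundled reference re-docking profiles, the PAINS + Schiff-base
#' alert catalogs, affinity ceilings of 5000 nM per target and 1e8 nM^3
#' for the Ki product, pharmacophore tolerance 1.45 Angstrom with 50\%
#' support, and the strict tPSA/logP passive-BBB rule. Any deviation from
#' these defaults is echoed into the report header.
#'
#' @param library a `molecule_library` data.frame.
#' @param scores long score table (see [read_score_table()]): columns
#'   `compound_id`, `target`, `rigid_score`, `flexible_score`,
#'   `ki_lower_nM`, `ki_upper_nM`.
#' @param stages character vector of stages to run, in order, from:
#'   `score_gate_rigid`, `score_gate_flexible`, `substructure`,
#'   `affinity_gate`, `pharmacophore`, `bbb`, `toxicity`.
#' @param thresholds_rigid,thresholds_flexible named per-target score
#'   thresholds (kcal/mol).
#' @param catalogs alert catalogs for the substructure stage.
#' @param per_target_max,product_max affinity ceilings (nM, nM^3; strict).
#' @param pose_features named list (by target) of named lists (by
#'   compound) of pose feature data.frames, for the pharmacophore stage.
#' @param pharmacophore_models optional pre-built consensus models (named
#'   by target); when absent, models are built from the pose features of
#'   the compounds entering the stage.
#' @param tolerance_A,support_threshold consensus pharmacophore settings.
#' @param bbb_labels data.frame (`compound_id`, `model`, `label`) of
#'   external BBB predictions.
#' @param use_bbb_rule also compute the tPSA/logP rule from the library
#'   structures and add it as a model (`physchem_rule`) before consensus.
#' @param tox_annotations data.frame (`compound_id`, `endpoint`,
#'   `likelihood`).
#' @param tox_action `"annotate"` (default; flagged hits stay, annotated)
#'   or `"remove"`.
#' @param tox_threshold likelihood threshold for flagging.
#' @param seed top-level seed recorded in the report (the cascade itself is
#'   deterministic; only synthetic-library generation is stochastic).
#' @return object of class `cascade_config`.
#' @export
cascade_config <- function(library, scores = NULL,
                           stages = c("score_gate_rigid",
                                      "score_gate_flexible",
                                      "substructure", "affinity_gate",
                                      "pharmacophore", "bbb", "toxicity"),
                           thresholds_rigid = reference_thresholds("rigid"),
                           thresholds_flexible = reference_thresholds("flexible"),
                           catalogs = default_catalogs(),
                           per_target_max = 5000, product_max = 1e8,
                           pose_features = NULL,
                           pharmacophore_models = NULL,
                           tolerance_A = 1.45, support_threshold = 0.5,
                           bbb_labels = NULL, use_bbb_rule = FALSE,
                           tox_annotations = NULL,
                           tox_action = c("annotate", "remove"),
                           tox_threshold = "plausible", seed = NULL) {
  tox_action <- match.arg(tox_action)
  known <- c("score_gate_rigid", "score_gate_flexible", "substructure",
             "affinity_gate", "pharmacophore", "bbb", "toxicity")
  bad <- setdiff(stages, known)
  if (length(bad)) stopf("unknown stage(s): %s", paste(bad, collapse = ", "))
  cfg <- structure(list(
    library = library, scores = scores, stages = stages,
    thresholds_rigid = thresholds_rigid,
    thresholds_flexible = thresholds_flexible, catalogs = catalogs,
    per_target_max = per_target_max, product_max = product_max,
    pose_features = pose_features,
    pharmacophore_models = pharmacophore_models,
    tolerance_A = tolerance_A, support_threshold = support_threshold,
    bbb_labels = bbb_labels, use_bbb_rule = use_bbb_rule,
    tox_annotations = tox_annotations, tox_action = tox_action,
    tox_threshold = tox_threshold, seed = seed), class = "cascade_config")
  validate_config(cfg)
  cfg
}

# abort before any stage runs if an enabled stage lacks its input
validate_config <- function(cfg) {
  if (!is.data.frame(cfg$library) || !"compound_id" %in% names(cfg$library))
    stopf("config: 'library' must be a molecule_library data.frame")
  for (st in cfg$stages) {
    switch(st,
      score_gate_rigid = ,
      score_gate_flexible = {
        if (is.null(cfg$scores))
          stopf("stage '%s' enabled but no score table supplied", st)
        col <- sub("score_gate_", "", st)
        if (!paste0(col, "_score") %in% names(cfg$scores))
          stopf("stage '%s' enabled but score table lacks %s_score", st, col)
      },
      affinity_gate = {
        if (is.null(cfg$scores) ||
            !all(c("ki_lower_nM", "ki_upper_nM") %in% names(cfg$scores)))
          stopf("stage 'affinity_gate' enabled but no affinity bounds supplied")
      },
      pharmacophore = {
        if (is.null(cfg$pose_features) && is.null(cfg$pharmacophore_models))
          stopf("stage 'pharmacophore' enabled but no pose features or models supplied")
      },
      bbb = {
        if (is.null(cfg$bbb_labels) && !isTRUE(cfg$use_bbb_rule))
          stopf("stage 'bbb' enabled but no BBB labels supplied and use_bbb_rule is FALSE")
      },
      toxicity = NULL)
  }
  invisible(cfg)
}

#' Run the multi-stage hit-triage cascade
#'
#' Executes the configured stages in order — docking-score gates,
#' substructure alerts, affinity gate with rank fusion, consensus
#' pharmacophore filter, BBB consensus, toxicity gate — each stage seeing
#' only the survivors of the previous one. Every removed compound is
#' attributed to exactly one stage with a reason, so stage counts, removal
#' logs and final survivors always sum to the input library size. Given
#' the same configuration (and seed, for synthetic inputs) the final hit
#' list and report are identical.
#'
#' @param config a [cascade_config()].
#' @return object of class `cascade_report`: list with `stages`
#'   (data.frame: stage, n_in, n_out), `removals` (data.frame: stage,
#'   compound_id, reason), `hits` (final ranked hit table; carries
#'   `tox_flags` when the toxicity stage ran), `ranking` (the ranked table
#'   at the affinity stage, if run), `config`, `timestamp`.
#' @examples
#' lib <- generate_library(sim_params(n_compounds = 200, seed = 3))
#' rep <- run_cascade(cascade_config(lib$library, lib$scores,
#'   stages = c("score_gate_rigid", "score_gate_flexible", "substructure",
#'              "affinity_gate")))
#' rep$stages
#' @export
run_cascade <- function(config) {
  stopifnot(inherits(config, "cascade_config"))
  validate_config(config)
  cur <- config$library
  stages <- data.frame(stage = character(), n_in = integer(),
                       n_out = integer(), stringsAsFactors = FALSE)
  removals <- data.frame(stage = character(), compound_id = character(),
                         reason = character(), stringsAsFactors = FALSE)
  ranking <- NULL
  flagged <- character()

  log_stage <- function(name, n_in, n_out) {
    stages[nrow(stages) + 1L, ] <<- list(name, n_in, n_out)
  }
  log_removals <- function(name, ids, reasons) {
    if (!length(ids)) return()
    removals <<- rbind(removals, data.frame(
      stage = name, compound_id = ids, reason = reasons,
      stringsAsFactors = FALSE))
  }

  for (st in config$stages) {
    n_in <- nrow(cur)
    if (st %in% c("score_gate_rigid", "score_gate_flexible")) {
      proto <- sub("score_gate_", "", st)
      thr <- config[[paste0("thresholds_", proto)]]
      sub <- config$scores[config$scores$compound_id %in% cur$compound_id, ,
                           drop = FALSE]
      res <- triple_activity_filter(sub, thr, protocol = proto)
      unscored <- setdiff(cur$compound_id, config$scores$compound_id)
      keep <- setdiff(res$kept, unscored)
      log_removals(st, res$removed$compound_id,
                   paste0(res$removed$reason, " [",
                          res$removed$failed_targets, "]"))
      log_removals(st, unscored, rep("missing_target_score []",
                                     length(unscored)))
      cur <- cur[cur$compound_id %in% keep, , drop = FALSE]
    } else if (st == "substructure") {
      res <- filter_clean(cur, config$catalogs)
      if (nrow(res$removed)) {
        agg <- stats::aggregate(
          pattern ~ compound_id,
          data = data.frame(compound_id = res$removed$compound_id,
                            pattern = paste(res$removed$catalog,
                                            res$removed$pattern_id,
                                            sep = ":"),
                            stringsAsFactors = FALSE),
          FUN = paste, collapse = ";")
        log_removals(st, agg$compound_id, agg$pattern)
      }
      cur <- res$kept
    } else if (st == "affinity_gate") {
      sub <- config$scores[config$scores$compound_id %in% cur$compound_id, ,
                           drop = FALSE]
      has_ki <- !is.na(sub$ki_lower_nM) & !is.na(sub$ki_upper_nM)
      aff <- data.frame(compound_id = sub$compound_id[has_ki],
                        target = sub$target[has_ki],
                        ki_nM = ki_from_range(sub$ki_lower_nM[has_ki],
                                              sub$ki_upper_nM[has_ki]),
                        stringsAsFactors = FALSE)
      targets <- unique(config$scores$target)
      noki <- setdiff(cur$compound_id, aff$compound_id)
      res <- affinity_gate(aff, per_target_max = config$per_target_max,
                           product_max = config$product_max,
                           targets = targets)
      log_removals(st, res$removed$compound_id, res$removed$reason)
      log_removals(st, noki, rep("missing_ki", length(noki)))
      cur <- cur[cur$compound_id %in% res$kept, , drop = FALSE]
      ranking <- rank_by_product(res$ki)
    } else if (st == "pharmacophore") {
      feats <- lapply(config$pose_features, function(by_cpd)
        by_cpd[intersect(names(by_cpd), cur$compound_id)])
      models <- config$pharmacophore_models
      if (is.null(models)) {
        models <- lapply(stats::setNames(nm = names(feats)), function(tg)
          build_consensus(feats[[tg]], tolerance_A = config$tolerance_A,
                          support_threshold = config$support_threshold,
                          target = tg))
      }
      # every current compound must be judged, also those with no pose
      for (tg in names(models))
        feats[[tg]] <- c(feats[[tg]] %||% list(), stats::setNames(
          rep(list(NULL), sum(!cur$compound_id %in% names(feats[[tg]]))),
          setdiff(cur$compound_id, names(feats[[tg]]))))
      res <- multi_target_pharmacophore_filter(feats, models,
                                               tolerance_A = config$tolerance_A)
      log_removals(st, res$removed$compound_id, res$removed$reason)
      cur <- cur[cur$compound_id %in% res$kept, , drop = FALSE]
    } else if (st == "bbb") {
      labels <- config$bbb_labels
      if (isTRUE(config$use_bbb_rule)) {
        rule <- data.frame(
          compound_id = cur$compound_id, model = "physchem_rule",
          label = passive_bbb_rule(compute_tpsa(cur$smiles),
                                   compute_logp(cur$smiles)),
          stringsAsFactors = FALSE)
        labels <- rbind(labels[, c("compound_id", "model", "label")], rule)
      }
      labels <- labels[labels$compound_id %in% cur$compound_id, ,
                       drop = FALSE]
      cons <- consensus_bbb(labels[, c("compound_id", "label")])
      keep <- cons$compound_id[cons$consensus == "penetrant"]
      nolabel <- setdiff(cur$compound_id, cons$compound_id)
      out_ids <- setdiff(cons$compound_id, keep)
      log_removals(st, out_ids, rep("bbb_non_penetrant", length(out_ids)))
      log_removals(st, nolabel, rep("missing_bbb_label", length(nolabel)))
      cur <- cur[cur$compound_id %in% keep, , drop = FALSE]
    } else if (st == "toxicity") {
      res <- toxicity_gate(cur, config$tox_annotations,
                           likelihood_threshold = config$tox_threshold,
                           action = config$tox_action)
      log_removals(st, res$removed$compound_id,
                   paste0("toxicity_alert [", res$removed$reason, "]"))
      flagged <- res$flagged
      cur <- res$kept
    }
    log_stage(st, n_in, nrow(cur))
  }

  hits <- cur
  if (!is.null(ranking)) {
    final <- ranking[ranking$compound_id %in% hits$compound_id, ,
                     drop = FALSE]
    final$rank <- seq_len(nrow(final))
    hits <- merge(final, as.data.frame(hits), by = "compound_id",
                  sort = FALSE)
    hits <- hits[order(hits$rank), , drop = FALSE]
    rownames(hits) <- NULL
  }
  structure(list(stages = stages, removals = removals, hits = hits,
                 ranking = ranking, flagged = flagged, config = config,
                 timestamp = format(Sys.time(), tz = "UTC",
                                    usetz = TRUE)),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Multi-target hit-triage cascade report\n")
  cat(sprintf("  run at: %s\n", x$timestamp))
  if (!is.null(x$config$seed)) cat(sprintf("  seed:   %s\n",
                                           format(x$config$seed)))
  cat(sprintf("  input library: %d compound(s)\n\n",
              if (nrow(x$stages)) x$stages$n_in[1] else nrow(x$hits)))
  print(x$stages, row.names = FALSE)
  cat(sprintf("\nFinal hits: %d", nrow(x$hits)))
  if (length(x$flagged))
    cat(sprintf(" (%d carrying toxicity flags)", length(x$flagged)))
  cat("\n")
  invisible(x)
}

#' @export
summary.cascade_report <- function(object, ...) {
  print(object)
  if (nrow(object$removals)) {
    cat("\nRemovals by stage and reason:\n")
    tab <- stats::aggregate(compound_id ~ stage + reason,
                            data = object$removals, FUN = length)
    names(tab)[3] <- "n"
    print(tab[order(tab$stage), ], row.names = FALSE)
  }
  invisible(object)
}

#' Write a cascade report to disk
#'
#' `"text"` writes a human-readable stage table (same layout as
#' `print()`); `"csv"` writes the machine-readable stage table, and the
#' removal log next to it as `<path>_removals.csv`.
#'
#' @param report a `cascade_report`.
#' @param path output file.
#' @param format `"text"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("text", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "cascade_report"))
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    sink(con)
    print(report)
    sink()
  } else {
    utils::write.csv(report$stages, path, row.names = FALSE)
    utils::write.csv(report$removals,
                     sub("(\\.[^.]*)?$", "_removals.csv",
                         path)[1],
                     row.names = FALSE)
  }
  invisible(path)
}
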