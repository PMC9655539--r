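#' Perceive typed pharmacophore features from a 3D pose
#'
#' Derives abstract interaction points from a docked pose, using the
#' feature vocabulary `aromatic_hydrophobic`, `hbond_donor`,
#' `hbond_acceptor`, `positive_ionizable` (the `hbond_either` type appears
#' only in consensus models). The definitions are structural:
#' \itemize{
#'   \item aromatic rings give one `aromatic_hydrophobic` feature at the
#'     ring centroid; all-carbon aliphatic rings likewise (hydrophobic and
#'     aromatic points share one merged type).
#'   \item N/O atoms with an explicit attached hydrogen give `hbond_donor`
#'     at the heteroatom position (poses must carry explicit hydrogens for
#'     donors to be seen).
#'   \item N/O atoms with a lone pair give `hbond_acceptor`, excluding
#'     amide/sulfonamide-type N (single-bonded to a C or S that is
#'     double-bonded to O/S), aromatic N-H, and positively charged atoms.
#'   \item formally positive atoms give `positive_ionizable` at the atom
#'     position.
#' }
#' Poses are assumed already posed in a fixed binding-site frame; no
#' superposition is performed.
#'
#' @param pose a pose as returned by [read_poses()] (a list with `atoms`,
#'   `bonds`, `sdf`).
#' @return data.frame with columns `feature_type`, `x`, `y`, `z`; zero
#'   rows if the structure presents no features.
#' @export
perceive_features <- function(pose) {
  if (is.null(pose$atoms) || is.null(pose$bonds))
    stopf("no pose: feature perception needs 3D coordinates")
  at <- pose$atoms
  bd <- pose$bonds
  feats <- list(data.frame(feature_type = character(), x = numeric(),
                           y = numeric(), z = numeric(),
                           stringsAsFactors = FALSE))

  # ring features via ChemmineR ring perception on the underlying SDF
  if (!is.null(pose$sdf)) {
    rg <- tryCatch(ChemmineR::rings(pose$sdf, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(rg) && length(rg$RINGS)) {
      for (i in seq_along(rg$RINGS)) {
        idx <- as.integer(sub("^[^_]+_", "", rg$RINGS[[i]]))
        elems <- at$element[idx]
        aromatic <- isTRUE(rg$AROMATIC[[i]])
        carbocycle <- all(elems == "C")
        if (aromatic || carbocycle)
          feats[[length(feats) + 1L]] <- data.frame(
            feature_type = "aromatic_hydrophobic",
            x = mean(at$x[idx]), y = mean(at$y[idx]), z = mean(at$z[idx]),
            stringsAsFactors = FALSE)
      }
    }
  }

  # adjacency helpers
  nbrs <- function(i) c(bd$a2[bd$a1 == i], bd$a1[bd$a2 == i])
  bond_order <- function(i, j) {
    o <- bd$order[(bd$a1 == i & bd$a2 == j) | (bd$a1 == j & bd$a2 == i)]
    if (length(o)) o[1] else 0
  }
  in_aromatic_ring <- rep(FALSE, nrow(at))
  if (!is.null(pose$sdf)) {
    rg <- tryCatch(ChemmineR::rings(pose$sdf, type = "all", arom = TRUE),
                   error = function(e) NULL)
    if (!is.null(rg) && length(rg$RINGS))
      for (i in seq_along(rg$RINGS))
        if (isTRUE(rg$AROMATIC[[i]]))
          in_aromatic_ring[as.integer(sub("^[^_]+_", "",
                                          rg$RINGS[[i]]))] <- TRUE
  }

  for (i in which(at$element %in% c("N", "O"))) {
    nb <- nbrs(i)
    has_h <- any(at$element[nb] == "H")
    positive <- at$charge[i] > 0
    if (has_h && !positive)
      feats[[length(feats) + 1L]] <- data.frame(
        feature_type = "hbond_donor", x = at$x[i], y = at$y[i], z = at$z[i],
        stringsAsFactors = FALSE)
    # acceptor: exclude amide-type N, aromatic N-H, cations
    amide_like <- at$element[i] == "N" && any(vapply(nb, function(j) {
      at$element[j] %in% c("C", "S") && bond_order(i, j) == 1 &&
        any(vapply(setdiff(nbrs(j), i), function(kk)
          at$element[kk] %in% c("O", "S") && bond_order(j, kk) == 2,
          logical(1)))
    }, logical(1)))
    pyrrole_like <- at$element[i] == "N" && in_aromatic_ring[i] && has_h
    if (!positive && !amide_like && !pyrrole_like)
      feats[[length(feats) + 1L]] <- data.frame(
        feature_type = "hbond_acceptor", x = at$x[i], y = at$y[i],
        z = at$z[i], stringsAsFactors = FALSE)
  }

  pos <- which(at$charge > 0)
  for (i in pos)
    feats[[length(feats) + 1L]] <- data.frame(
      feature_type = "positive_ionizable", x = at$x[i], y = at$y[i],
      z = at$z[i], stringsAsFactors = FALSE)

  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  out
}

feature_types <- c("aromatic_hydrophobic", "hbond_donor", "hbond_acceptor",
                   "hbond_either", "positive_ionizable")

# Euclidean distance from points (matrix nx3) to a centroid (length 3).
dist_to <- function(xyz, centre) {
  sqrt(colSums((t(xyz) - centre)^2))
}

#' Build a consensus pharmacophore model from per-ligand feature sets
#'
#' Clusters same-type features across the posed ligands of one target:
#' features whose positions agree within the neighborhood distance
#' tolerance are merged into one consensus feature at their centroid, and
#' a consensus feature is retained iff the fraction of ligands supporting
#' it (at most one feature per ligand per cluster) is at least
#' `support_threshold`. Defaults are tolerance 1.45 Angstrom and threshold
#' 50\%; the threshold comparison is `>=`, so a feature present in exactly
#' half the ligands survives.
#'
#' Clustering is greedy centroid-linkage per feature type: seed with the
#' feature having the densest neighborhood, assign at most one feature per
#' ligand within tolerance of the seed, recompute the centroid and drop
#' members that fall outside tolerance of it (so every retained member
#' lies within tolerance of the final centroid), remove the cluster and
#' repeat. Ties are broken by ligand order, then coordinate-lexicographic
#' order, making the procedure deterministic.
#'
#' @param feature_sets named list of per-ligand feature data.frames
#'   (`feature_type`, `x`, `y`, `z`), all poses in one common reference
#'   frame.
#' @param tolerance_A neighborhood distance tolerance in Angstrom (> 0).
#' @param support_threshold minimum supporting-ligand fraction in `(0, 1]`.
#' @param target target name recorded in the model.
#' @return object of class `consensus_model`: list with `target`,
#'   `features` (data.frame: feature_id, feature_type, x, y, z, support),
#'   `n_ligands`, `tolerance_A`, `support_threshold`.
#' @examples
#' arch <- data.frame(feature_type = c("aromatic_hydrophobic", "hbond_donor"),
#'                    x = c(0, 3), y = 0, z = 0)
#' sets <- generate_pose_features(5, arch, jitter_sd = 0)
#' build_consensus(sets)$features
#' @export
build_consensus <- function(feature_sets, tolerance_A = 1.45,
                            support_threshold = 0.5, target = "target") {
  if (!length(feature_sets)) stopf("empty input: no ligand feature sets")
  stopifnot(tolerance_A > 0, support_threshold > 0, support_threshold <= 1)
  if (is.null(names(feature_sets)))
    names(feature_sets) <- paste0("L", seq_along(feature_sets))
  n_lig <- length(feature_sets)

  pool_all <- do.call(rbind, lapply(names(feature_sets), function(lg) {
    f <- feature_sets[[lg]]
    if (!nrow(f)) return(NULL)
    data.frame(ligand = lg, lig_idx = match(lg, names(feature_sets)),
               feature_type = f$feature_type, x = f$x, y = f$y, z = f$z,
               stringsAsFactors = FALSE)
  }))
  clusters <- list()
  for (tp in unique(pool_all$feature_type)) {
    pool <- pool_all[pool_all$feature_type == tp, , drop = FALSE]
    # deterministic candidate order: ligand order, then coordinates
    pool <- pool[order(pool$lig_idx, pool$x, pool$y, pool$z), , drop = FALSE]
    while (nrow(pool)) {
      xyz <- as.matrix(pool[, c("x", "y", "z")])
      # neighborhood size of each candidate seed (<=1 per ligand)
      dens <- vapply(seq_len(nrow(pool)), function(i) {
        d <- dist_to(xyz, xyz[i, ])
        length(unique(pool$lig_idx[d <= tolerance_A]))
      }, integer(1))
      seed <- which.max(dens)  # first max wins: deterministic tie-break
      centre <- xyz[seed, ]
      members <- integer()
      for (rep_i in 1:10) {
        d <- dist_to(xyz, centre)
        cand <- which(d <= tolerance_A)
        # one feature per ligand: nearest wins
        cand <- cand[order(pool$lig_idx[cand], d[cand])]
        cand <- cand[!duplicated(pool$lig_idx[cand])]
        new_centre <- colMeans(xyz[cand, , drop = FALSE])
        # keep only members still within tolerance of the final centroid
        cand <- cand[dist_to(xyz[cand, , drop = FALSE],
                             new_centre) <= tolerance_A]
        if (length(cand) == 0L) { cand <- seed; new_centre <- xyz[seed, ] }
        if (identical(cand, members) &&
            sum(abs(new_centre - centre)) < 1e-12) break
        members <- cand
        centre <- colMeans(xyz[members, , drop = FALSE])
      }
      clusters[[length(clusters) + 1L]] <- data.frame(
        feature_type = tp, x = centre[1], y = centre[2], z = centre[3],
        support = length(unique(pool$lig_idx[members])),
        stringsAsFactors = FALSE)
      pool <- pool[-members, , drop = FALSE]
    }
  }
  feats <- do.call(rbind, clusters)
  feats <- feats[feats$support / n_lig >= support_threshold, , drop = FALSE]
  if (is.null(feats) || !nrow(feats)) {
    feats <- data.frame(feature_type = character(), x = numeric(),
                        y = numeric(), z = numeric(), support = integer(),
                        stringsAsFactors = FALSE)
  }
  feats <- feats[order(feats$feature_type, feats$x, feats$y, feats$z), ,
                 drop = FALSE]
  feats <- data.frame(feature_id = if (nrow(feats))
    paste0("F", seq_len(nrow(feats))) else character(), feats,
    stringsAsFactors = FALSE)
  rownames(feats) <- NULL
  structure(list(target = target, features = feats, n_ligands = n_lig,
                 tolerance_A = tolerance_A,
                 support_threshold = support_threshold),
            class = "consensus_model")
}

#' @export
print.consensus_model <- function(x, ...) {
  cat(sprintf(paste0("<consensus_model '%s': %d feature(s) from %d ",
                     "ligand(s), tolerance %.2f A, support >= %.0f%%>\n"),
              x$target, nrow(x$features), x$n_ligands, x$tolerance_A,
              100 * x$support_threshold))
  if (nrow(x$features)) print(x$features, row.names = FALSE)
  invisible(x)
}

# can a ligand feature of type `have` satisfy a model feature of type `need`?
type_compatible <- function(need, have) {
  if (need == "hbond_either")
    return(have %in% c("hbond_donor", "hbond_acceptor", "hbond_either"))
  if (have == "hbond_either")
    return(need %in% c("hbond_donor", "hbond_acceptor"))
  need == have
}

#' Does a ligand match every consensus feature?
#'
#' TRUE iff for every feature of the consensus model there is a ligand
#' feature of compatible type within `tolerance_A` of the feature
#' centroid (`hbond_either` is satisfied by a donor or an acceptor). This
#' is the match-all selection rule: a compound is a pharmacophore hit for
#' a target only if it covers the target's full consensus model.
#'
#' @param features ligand feature data.frame (`feature_type`, `x`, `y`,
#'   `z`).
#' @param model a [build_consensus()] model.
#' @param tolerance_A match tolerance; defaults to the model's own.
#' @return logical scalar.
#' @export
match_all_features <- function(features, model,
                               tolerance_A = model$tolerance_A) {
  stopifnot(inherits(model, "consensus_model"))
  mf <- model$features
  if (!nrow(mf)) return(TRUE)
  if (is.null(features) || !nrow(features)) return(FALSE)
  xyz <- as.matrix(features[, c("x", "y", "z")])
  for (i in seq_len(nrow(mf))) {
    compat <- vapply(features$feature_type, type_compatible,
                     logical(1), need = mf$feature_type[i])
    if (!any(compat)) return(FALSE)
    d <- dist_to(xyz[compat, , drop = FALSE],
                 c(mf$x[i], mf$y[i], mf$z[i]))
    if (!any(d <= tolerance_A)) return(FALSE)
  }
  TRUE
}

#' Multi-target consensus pharmacophore filter
#'
#' A compound survives iff it matches every consensus feature of every
#' target's model, each evaluated on the compound's pose features for that
#' target. Compounds lacking features for some target are removed and
#' logged.
#'
#' @param feature_sets_by_target named list (by target) of named lists (by
#'   compound id) of ligand feature data.frames.
#' @param models named list (by target) of `consensus_model` objects; every
#'   target in `models` must appear in `feature_sets_by_target`.
#' @param tolerance_A optional override of each model's match tolerance.
#' @return list with `kept` (compound ids) and `removed` (data.frame:
#'   compound_id, reason).
#' @export
multi_target_pharmacophore_filter <- function(feature_sets_by_target, models,
                                              tolerance_A = NULL) {
  miss <- setdiff(names(models), names(feature_sets_by_target))
  if (length(miss))
    stopf("no pose features for target(s): %s", paste(miss, collapse = ", "))
  ids <- unique(unlist(lapply(feature_sets_by_target, names)))
  removed <- list()
  kept <- character()
  for (id in ids) {
    fail <- character()
    for (tg in names(models)) {
      f <- feature_sets_by_target[[tg]][[id]]
      tol <- tolerance_A %||% models[[tg]]$tolerance_A
      if (is.null(f)) {
        fail <- c(fail, paste0(tg, ":no_pose"))
      } else if (!match_all_features(f, models[[tg]], tol)) {
        fail <- c(fail, paste0(tg, ":feature_mismatch"))
      }
    }
    if (length(fail)) {
      removed[[length(removed) + 1L]] <- data.frame(
        compound_id = id, reason = paste(fail, collapse = ";"),
        stringsAsFactors = FALSE)
    } else kept <- c(kept, id)
  }
  removed <- if (length(removed)) do.call(rbind, removed)
             else data.frame(compound_id = character(),
                             reason = character(), stringsAsFactors = FALSE)
  list(kept = kept, removed = removed)
}
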