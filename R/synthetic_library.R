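#' Simulation parameters for a synthetic screening library
#'
#' Defines the statistical structure of a mock library plus per-target
#' score tables, emulating what a docking campaign hands to the triage
#' cascade: correlated per-target docking scores (more negative = better,
#' matching the docking convention), lognormal predicted-affinity ranges,
#' a planted fraction of guaranteed triple-actives, and a planted fraction
#' of PAINS-bearing contaminants.
#'
#' Background compounds are drawn so that passing all gates by chance is
#' vanishingly rare: docking scores are multivariate normal across the
#' targets with correlation `rho` and means well above (worse than) the
#' reference thresholds, and affinities are lognormal with median 50 uM —
#' an inactive library. Planted actives instead score strictly below every
#' threshold and receive affinity ranges satisfying both affinity
#' constraints by construction, so filters applied to noise-free planted
#' data must retrieve them with zero false negatives.
#'
#' @param n_compounds library size (>= 0).
#' @param seed integer seed; identical params + seed give identical tables.
#' @param score_mean,score_sd named lists with elements `rigid` and
#'   `flexible`: background score mean/sd per protocol (scalar, or a named
#'   per-target vector), kcal/mol-scaled.
#' @param rho cross-target score correlation in `[-1, 1]`.
#' @param ki_log_median,ki_log_sd background affinity distribution: natural
#'   log of the median Ki in nM, and log-sd.
#' @param p_active planted triple-active fraction in `[0, 1]`.
#' @param q_pains planted PAINS-contaminant fraction in `[0, 1]`
#'   (contaminants are drawn from the background, never from the planted
#'   actives).
#' @param ki_spread affinity-range spread factor phi > 1: ranges are
#'   `(Ki/phi, Ki*phi)`, so the geometric mean recovers the generating Ki
#'   exactly.
#' @param thresholds named list with per-target threshold vectors `rigid`
#'   and `flexible` that planted actives must beat; defaults to the
#'   bundled reference-ligand thresholds ([reference_thresholds()]).
#' @return object of class `sim_params`.
#' @seealso [generate_library()]
#' @export
sim_params <- function(n_compounds = 5000, seed = 1,
                       score_mean = list(rigid = -9, flexible = -5.5),
                       score_sd = list(rigid = 1.5, flexible = 1.0),
                       rho = 0.3,
                       ki_log_median = log(5e4), ki_log_sd = 1.2,
                       p_active = 0.02, q_pains = 0.05,
                       ki_spread = 3,
                       thresholds = list(
                         rigid = reference_thresholds("rigid"),
                         flexible = reference_thresholds("flexible"))) {
  if (n_compounds < 0) stopf("n_compounds must be >= 0")
  for (f in c(p_active, q_pains))
    if (f < 0 || f > 1) stopf("fractions must lie in [0, 1]")
  if (abs(rho) > 1) stopf("rho must lie in [-1, 1]")
  if (ki_spread <= 1) stopf("ki_spread must be > 1")
  if (!all(c("rigid", "flexible") %in% names(thresholds)))
    stopf("thresholds must have 'rigid' and 'flexible' components")
  if (p_active > 0 && !all(vapply(thresholds, function(t)
      all(is.finite(t)), logical(1))))
    stopf("infeasible params: p_active > 0 with non-finite thresholds")
  structure(list(n_compounds = as.integer(n_compounds), seed = seed,
                 score_mean = score_mean, score_sd = score_sd, rho = rho,
                 ki_log_median = ki_log_median, ki_log_sd = ki_log_sd,
                 p_active = p_active, q_pains = q_pains,
                 ki_spread = ki_spread, thresholds = thresholds),
            class = "sim_params")
}

# Small redistributable SMILES fragment grammar: core(linker + tail).
frag_cores <- c("c1ccc(%s)cc1", "c1ccnc(%s)c1", "c1ccc(%s)c(OC)c1",
                "c1cc(C)ccc1%s", "c1cc(F)ccc1%s", "c1ccc2ccccc2c1%s")
frag_linkers <- c("CC(=O)N", "S(=O)(=O)N", "OCC(=O)N", "C(=O)N", "CN",
                  "OC", "CCN", "C(=O)OC", "CSC", "CC(O)C")
frag_tails <- c("c2ccccc2", "c2ccncc2", "c2ccc(F)cc2", "c2ccc(OC)cc2",
                "c2ccc(Cl)cc2", "C2CCCCC2", "C2CCNCC2", "CC", "C(C)C")
# PAINS-bearing contaminant structures (each matches a bundled pattern).
frag_contaminants <- c("O=C1C(Cc2ccccc2)SC(=S)N1",
                       "O=C1C(=Cc2ccccc2)SC(=S)N1",
                       "Oc1ccccc1O",
                       "Oc1ccccc1CN(C)C",
                       "O=C1NC(=O)NC(=O)C1=Cc1ccccc1")

grammar_smiles <- function(n) {
  if (n == 0L) return(character())
  sprintf(sample(frag_cores, n, replace = TRUE),
          paste0(sample(frag_linkers, n, replace = TRUE),
                 sample(frag_tails, n, replace = TRUE)))
}

# Correlated N(0,1) draws: n x k with common pairwise correlation rho.
corr_normal <- function(n, k, rho) {
  if (n == 0L) return(matrix(numeric(), 0L, k))
  sigma <- matrix(rho, k, k); diag(sigma) <- 1
  z <- matrix(stats::rnorm(n * k), n, k)
  z %*% chol(sigma)
}

#' Generate a synthetic library with per-target score tables
#'
#' Draws a mock compound library and the score tables the cascade
#' consumes, with the structure described in [sim_params()]. Planted
#' triple-actives (fraction `p_active`, Bernoulli per compound) are
#' guaranteed to pass every docking-score gate and both affinity
#' constraints; planted contaminants (fraction `q_pains`, background
#' compounds only) carry a PAINS-matching substructure. Identical
#' parameters and seed give identical output.
#'
#' @param params a [sim_params()] object.
#' @return list of class `synthetic_library`: `library` (a
#'   `molecule_library`), `scores` (long data.frame: compound_id, target,
#'   rigid_score, flexible_score, ki_lower_nM, ki_upper_nM), `planted`
#'   and `contaminated` (compound id vectors), `params`.
#' @examples
#' lib <- generate_library(sim_params(n_compounds = 50, seed = 7))
#' nrow(lib$library)
#' @export
generate_library <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_compounds
  targets <- names(params$thresholds$rigid)
  k <- length(targets)
  with_seed(params$seed, {
    ids <- if (n > 0) sprintf("SYN%05d", seq_len(n)) else character()
    planted <- stats::runif(n) < params$p_active
    background_ids <- which(!planted)
    contam <- logical(n)
    if (length(background_ids))
      contam[background_ids] <-
        stats::runif(length(background_ids)) < params$q_pains

    smiles <- grammar_smiles(n)
    if (any(contam))
      smiles[contam] <- sample(frag_contaminants, sum(contam),
                               replace = TRUE)

    score_cols <- list()
    for (proto in c("rigid", "flexible")) {
      mu <- rep(params$score_mean[[proto]], length.out = k)
      sd <- rep(params$score_sd[[proto]], length.out = k)
      sc <- corr_normal(n, k, params$rho)
      sc <- sweep(sweep(sc, 2, sd, `*`), 2, mu, `+`)
      thr <- params$thresholds[[proto]][targets]
      if (any(planted)) {
        np <- sum(planted)
        margins <- matrix(stats::runif(np * k, 0.25, 2), np, k)
        sc[planted, ] <- rep(thr, each = np) - margins
      }
      score_cols[[proto]] <- sc
    }

    ki <- matrix(exp(params$ki_log_median +
                       params$ki_log_sd * stats::rnorm(n * k)), n, k)
    if (any(planted)) {
      np <- sum(planted)
      kp <- matrix(exp(stats::runif(np * k, log(5), log(2000))), np, k)
      over <- apply(kp, 1L, prod) >= 9e7
      if (any(over)) {
        scale <- (9e7 / apply(kp[over, , drop = FALSE], 1L, prod))^(1 / k)
        kp[over, ] <- kp[over, ] * scale * 0.999
      }
      ki[planted, ] <- kp
    }

    scores <- data.frame(
      compound_id = rep(ids, times = k),
      target = rep(targets, each = n),
      rigid_score = as.vector(score_cols$rigid),
      flexible_score = as.vector(score_cols$flexible),
      ki_lower_nM = as.vector(ki) / params$ki_spread,
      ki_upper_nM = as.vector(ki) * params$ki_spread,
      stringsAsFactors = FALSE)

    structure(list(library = as_molecule_library(ids, smiles),
                   scores = scores,
                   planted = ids[planted],
                   contaminated = ids[contam],
                   params = params),
              class = "synthetic_library")
  })
}

#' @export
print.synthetic_library <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_library: %d compounds, %d planted ",
                     "triple-active(s), %d contaminant(s), seed %s>\n"),
              nrow(x$library), length(x$planted), length(x$contaminated),
              format(x$params$seed)))
  invisible(x)
}

#' Write a synthetic library to the file formats the readers consume
#'
#' Writes `library.csv` (readable by [read_molecule_table()]) and
#' `scores.csv` (readable by [read_score_table()]) into `dir`.
#'
#' @param lib a `synthetic_library`.
#' @param dir output directory (created if needed).
#' @return named character vector of the two paths, invisibly.
#' @export
write_library <- function(lib, dir) {
  stopifnot(inherits(lib, "synthetic_library"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib_path <- file.path(dir, "library.csv")
  sc_path <- file.path(dir, "scores.csv")
  write_molecule_table(lib$library, lib_path)
  utils::write.csv(lib$scores, sc_path, row.names = FALSE)
  invisible(c(library = lib_path, scores = sc_path))
}

#' Generate per-ligand pharmacophore feature sets around an archetype
#'
#' Test harness for consensus pharmacophore building: each simulated
#' ligand's feature set is the archetype's typed centroids plus isotropic
#' Gaussian positional jitter of `jitter_sd` Angstrom. With zero jitter
#' every set equals the archetype exactly.
#'
#' @param n_ligands number of ligands.
#' @param archetype data.frame with columns `feature_type`, `x`, `y`, `z`.
#' @param jitter_sd per-coordinate Gaussian jitter in Angstrom.
#' @param seed integer seed (deterministic per seed).
#' @return named list (`L1..Ln`) of feature data.frames.
#' @seealso [build_consensus()]
#' @export
generate_pose_features <- function(n_ligands, archetype, jitter_sd = 0,
                                   seed = 1) {
  stopifnot(n_ligands >= 1,
            all(c("feature_type", "x", "y", "z") %in% names(archetype)))
  with_seed(seed, {
    out <- lapply(seq_len(n_ligands), function(i) {
      f <- archetype[, c("feature_type", "x", "y", "z")]
      m <- nrow(f)
      f$x <- f$x + stats::rnorm(m, 0, jitter_sd)
      f$y <- f$y + stats::rnorm(m, 0, jitter_sd)
      f$z <- f$z + stats::rnorm(m, 0, jitter_sd)
      f
    })
    names(out) <- paste0("L", seq_len(n_ligands))
    out
  })
}
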