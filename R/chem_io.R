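#' Canonical structure key for a SMILES string
#'
#' Maps any valid SMILES encoding of a molecule to a canonical SMILES key,
#' so that two encodings of the same structure (including its charge state)
#' compare equal. Charged atoms written in brackets (e.g. `[NH+]`) are kept
#' as written; no neutralization or protonation-state enumeration is done,
#' since screening libraries are typically supplied already protonated at
#' physiological pH.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES keys, same length as input.
#' @examples
#' canonical_key(c("c1ccccc1", "C1=CC=CC=C1"))  # same key twice
#' @export
canonical_key <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    can <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s))
    sub("[\t\n ].*$", "", can)
  }, character(1), USE.NAMES = FALSE)
  bad <- !is.na(smiles) & nzchar(trimws(smiles)) & !nzchar(out)
  if (any(bad))
    stopf("invalid structure(s): %s",
          paste(utils::head(smiles[bad], 5L), collapse = ", "))
  out
}

# TRUE for SMILES OpenBabel can parse; quiet, never throws.
is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(FALSE)
    nzchar(sub("[\t\n ].*$", "",
               suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s))))
  }, logical(1), USE.NAMES = FALSE)
}

#' Read a compound library from a SMILES table or SDF file
#'
#' Reads one record per entry, validates every structure, computes a
#' canonical key at ingest, and (by default) collapses duplicate structures
#' with a warning, so that downstream accounting operates on unique
#' compounds. Invalid entries are skipped and reported with their
#' line/record index.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"smiles"` (delimited table with a
#'   SMILES column) or `"sdf"`.
#' @param smiles_col,id_col,name_col column names used for `"smiles"` format.
#'   If `id_col` is absent from the file, ids `CPD1..CPDn` are assigned.
#' @param delim field delimiter for `"smiles"` format; default guesses
#'   between comma and tab from the header line.
#' @param dedupe collapse records whose canonical keys coincide (first
#'   occurrence wins) with a warning.
#' @return a `molecule_library`: a data.frame with columns `compound_id`,
#'   `smiles`, `name`, `canonical_key`, plus any further columns of the
#'   input carried along as annotations. Zero valid records yields an empty
#'   library (0 rows) with a warning.
#' @seealso [write_molecule_table()], [read_score_table()]
#' @export
read_molecule_table <- function(path, format = c("auto", "smiles", "sdf"),
                                smiles_col = "smiles", id_col = "compound_id",
                                name_col = "name", delim = NULL,
                                dedupe = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("sdf", "mol"))
      "sdf" else "smiles"
  }
  if (format == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    smi <- vapply(seq_along(sdf), function(i) {
      tryCatch(sub("[\t\n ].*$", "",
                   suppressWarnings(ChemmineOB::convertFormat(
                     "SDF", "CAN",
                     paste(ChemmineR::sdf2str(sdf[[i]]), collapse = "\n")))),
               error = function(e) "")
    }, character(1))
    ids <- ChemmineR::sdfid(sdf)
    df <- data.frame(compound_id = ids, smiles = smi,
                     name = ids, stringsAsFactors = FALSE)
  } else {
    first <- readLines(path, n = 1L)
    if (is.null(delim))
      delim <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE,
                          check.names = FALSE)
    if (!smiles_col %in% names(df))
      stopf("missing SMILES column '%s' in %s", smiles_col, path)
    names(df)[names(df) == smiles_col] <- "smiles"
    if (id_col %in% names(df)) {
      names(df)[names(df) == id_col] <- "compound_id"
    } else df$compound_id <- paste0("CPD", seq_len(nrow(df)))
    if (name_col %in% names(df)) {
      names(df)[names(df) == name_col] <- "name"
    } else df$name <- df$compound_id
  }
  if (nrow(df) == 0L) {
    warnf("no records in %s: empty library", path)
    return(empty_library())
  }
  ok <- is_valid_smiles(df$smiles)
  if (any(!ok))
    warnf("skipping %d invalid record(s) at index: %s", sum(!ok),
          paste(utils::head(which(!ok), 10L), collapse = ", "))
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) {
    warnf("zero valid records in %s: empty library", path)
    return(empty_library())
  }
  if (anyDuplicated(df$compound_id))
    stopf("duplicate compound_id in %s", path)
  df$canonical_key <- canonical_key(df$smiles)
  if (dedupe && anyDuplicated(df$canonical_key)) {
    dup <- duplicated(df$canonical_key)
    warnf("collapsing %d duplicate structure(s) by canonical key", sum(dup))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  core <- c("compound_id", "smiles", "name", "canonical_key")
  df <- df[, c(core, setdiff(names(df), core)), drop = FALSE]
  class(df) <- c("molecule_library", "data.frame")
  df
}

empty_library <- function() {
  df <- data.frame(compound_id = character(), smiles = character(),
                   name = character(), canonical_key = character(),
                   stringsAsFactors = FALSE)
  class(df) <- c("molecule_library", "data.frame")
  df
}

# Build a molecule_library from in-memory vectors (no file round trip).
as_molecule_library <- function(compound_id, smiles, name = compound_id,
                                key = FALSE) {
  df <- data.frame(compound_id = compound_id, smiles = smiles, name = name,
                   canonical_key = if (isTRUE(key)) canonical_key(smiles)
                                   else rep(NA_character_, length(smiles)),
                   stringsAsFactors = FALSE)
  class(df) <- c("molecule_library", "data.frame")
  df
}

#' Write a compound library to a SMILES table
#'
#' Inverse of [read_molecule_table()] for the `"smiles"` format: the written
#' file reads back with identical compound ids, canonical keys and
#' annotation columns.
#'
#' @param library a `molecule_library` data.frame.
#' @param path output file; delimiter chosen by extension (`.tsv` gives
#'   tab, anything else comma).
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(library, path) {
  stopifnot(is.data.frame(library))
  delim <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  out <- as.data.frame(library)
  out$canonical_key <- NULL
  utils::write.table(out, path, sep = delim, row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Read a per-compound, per-target score table
#'
#' Reads the CSV/TSV score tables the cascade consumes: one row per
#' (compound, target) with rigid and flexible docking scores (kcal/mol,
#' more negative is better) and an optional predicted-affinity range in nM.
#' Units are preserved as given. Rows with inverted affinity bounds
#' (`ki_lower_nM > ki_upper_nM`) are kept but flagged in the `ki_inverted`
#' column and reported with a warning. When a library is supplied, rows
#' whose `compound_id` is unknown are split off as orphans, so that
#' `nrow(input) == nrow(attached) + nrow(orphans)`.
#'
#' @param path CSV or TSV file with columns `compound_id`, `target`, and at
#'   least one of `rigid_score`, `flexible_score`, plus optional
#'   `ki_lower_nM`, `ki_upper_nM`.
#' @param library optional `molecule_library` used to detect orphan rows.
#' @param delim field delimiter; default guesses from the header.
#' @return data.frame of attached rows with an `orphans` attribute holding
#'   the unattached rows (empty when `library` is `NULL`).
#' @export
read_score_table <- function(path, library = NULL, delim = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE)
  need <- c("compound_id", "target")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("score table %s lacks mandatory column(s): %s", path,
          paste(miss, collapse = ", "))
  scorecols <- intersect(c("rigid_score", "flexible_score"), names(df))
  if (!length(scorecols))
    stopf("score table %s has neither rigid_score nor flexible_score", path)
  for (cl in c(scorecols, intersect(c("ki_lower_nM", "ki_upper_nM"), names(df)))) {
    if (!is.numeric(df[[cl]]))
      stopf("non-numeric values in column '%s' of %s", cl, path)
  }
  if (all(c("ki_lower_nM", "ki_upper_nM") %in% names(df))) {
    df$ki_inverted <- !is.na(df$ki_lower_nM) & !is.na(df$ki_upper_nM) &
      df$ki_lower_nM > df$ki_upper_nM
    if (any(df$ki_inverted))
      warnf("%d row(s) with ki_lower_nM > ki_upper_nM flagged in 'ki_inverted'",
            sum(df$ki_inverted))
  }
  orphans <- df[0, , drop = FALSE]
  if (!is.null(library)) {
    known <- df$compound_id %in% library$compound_id
    orphans <- df[!known, , drop = FALSE]
    if (nrow(orphans))
      warnf("%d orphan score row(s) with unknown compound_id", nrow(orphans))
    df <- df[known, , drop = FALSE]
  }
  rownames(df) <- rownames(orphans) <- NULL
  attr(df, "orphans") <- orphans
  df
}

#' Read docked poses from an SDF file
#'
#' Reads a V2000 SDF with one conformer per record, coordinates in
#' Angstrom. The target a pose belongs to is taken from an SDF data field
#' (default `target`). Formal charges are taken from the atom-block charge
#' codes and any `M  CHG` property lines. Whether the file carries explicit
#' hydrogens is detected and recorded (pose feature perception needs
#' explicit hydrogens to see donors).
#'
#' @param path SDF file.
#' @param target_field name of the SDF data field holding the target name.
#' @return named list (by record id) of poses; each pose is a list with
#'   `atoms` (data.frame: element, x, y, z, charge), `bonds` (data.frame:
#'   a1, a2, order), `target`, `sdf` (the underlying ChemmineR SDF object)
#'   and `explicit_h` (logical).
#' @export
read_poses <- function(path, target_field = "target") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sdfset <- ChemmineR::read.SDFset(path)
  chg_all <- scan_mchg(path)
  out <- lapply(seq_along(sdfset), function(i) {
    pose_from_sdf(sdfset[[i]], target_field = target_field,
                  mchg = chg_all[[i]])
  })
  names(out) <- make.unique(ChemmineR::sdfid(sdfset))
  out
}

# ChemmineR drops "M  CHG" lines; recover them per record from the raw file.
scan_mchg <- function(path) {
  lines <- readLines(path)
  rec_end <- grep("^\\${4}", lines)
  rec_start <- c(1L, utils::head(rec_end, -1L) + 1L)
  lapply(seq_along(rec_end), function(i) {
    block <- lines[rec_start[i]:rec_end[i]]
    chg <- grep("^M  CHG", block, value = TRUE)
    if (!length(chg)) return(NULL)
    vals <- lapply(chg, function(l) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", l)),
                               "\\s+")[[1]])
      matrix(f, ncol = 2, byrow = TRUE)
    })
    do.call(rbind, vals)  # columns: atom index, charge
  })
}

# Old-style V2000 atom-block charge codes -> formal charge.
charge_from_code <- function(code) {
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2,
           `7` = -3)
  unname(map[as.character(code)])
}

pose_from_sdf <- function(sdf, target_field = "target", mchg = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  coords <- ab[, 1:3, drop = FALSE]
  if (any(!is.finite(coords))) stopf("non-finite pose coordinates")
  charge <- rep(0L, nrow(ab))
  if (ncol(ab) >= 4) {
    code <- ab[, 4]
    charge <- charge_from_code(ifelse(is.finite(code), code, 0))
  }
  if (!is.null(mchg)) {
    charge[] <- 0L  # M CHG supersedes atom-block codes (V2000 rule)
    charge[mchg[, 1]] <- mchg[, 2]
  }
  bb <- ChemmineR::bondblock(sdf)
  bonds <- data.frame(a1 = bb[, 1], a2 = bb[, 2], order = bb[, 3])
  db <- ChemmineR::datablock(sdf)
  target <- if (target_field %in% names(db)) unname(db[[target_field]])
            else NA_character_
  list(atoms = data.frame(element = el, x = coords[, 1], y = coords[, 2],
                          z = coords[, 3], charge = as.integer(charge),
                          stringsAsFactors = FALSE),
       bonds = bonds, target = target, sdf = sdf,
       explicit_h = any(el == "H"))
}
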