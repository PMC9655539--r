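#' Compile a substructure alert catalog
#'
#' An alert catalog is a named set of SMARTS patterns whose match on a
#' compound flags it for removal: PAINS (pan-assay interference) families
#' and a Schiff-base (acyclic, hydrolytically labile imine) pattern are
#' bundled. Every SMARTS is compiled against a probe molecule at load
#' time, so invalid patterns fail immediately with the offending
#' `pattern_id` named.
#'
#' @param source a TSV file with columns `pattern_id`, `smarts`,
#'   `description`, or an equivalent data.frame.
#' @param name catalog name (e.g. `"pains"`, `"schiff_base"`, `"custom"`).
#' @return object of class `alert_catalog`.
#' @seealso [default_catalogs()] for the bundled catalogs.
#' @export
compile_catalog <- function(source, name = "custom") {
  df <- if (is.data.frame(source)) source
        else utils::read.delim(source, stringsAsFactors = FALSE)
  need <- c("pattern_id", "smarts")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("catalog lacks column(s): %s", paste(miss, collapse = ", "))
  if (!"description" %in% names(df)) df$description <- rep("", nrow(df))
  if (anyDuplicated(df$pattern_id))
    stopf("duplicate pattern_id in catalog '%s'", name)
  probe <- ChemmineR::smiles2sdf(c(probe = "CCO"))
  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({
      ChemmineR::smartsSearchOB(probe, df$smarts[i]); TRUE
    }, error = function(e) FALSE)
    if (!ok)
      stopf("invalid SMARTS for pattern_id '%s' in catalog '%s'",
            df$pattern_id[i], name)
  }
  structure(list(name = name,
                 patterns = df[, c("pattern_id", "smarts", "description")]),
            class = "alert_catalog")
}

#' @export
print.alert_catalog <- function(x, ...) {
  cat(sprintf("<alert_catalog '%s': %d pattern(s)>\n", x$name,
              nrow(x$patterns)))
  invisible(x)
}

#' Bundled alert catalogs
#'
#' Returns the catalogs shipped with the package: `pains`, a curated set of
#' SMARTS for the major published PAINS substructure families (rhodanines
#' and ene-rhodanines, quinones, catechols/hydroquinones, hydroxyphenyl
#' hydrazones, aryl azo, phenolic Mannich bases, alkylidene barbiturates,
#' conjugated Michael acceptors, and related reactive/redox motifs), and
#' `schiff_base`, an acyclic-imine pattern that excludes amidines,
#' guanidines and ring-embedded C=N (aromatic azines are stable; the alert
#' targets hydrolytically unstable imines). Any external pattern file in
#' the same TSV layout can be swapped in via [compile_catalog()].
#'
#' @return named list of `alert_catalog` objects.
#' @export
default_catalogs <- function() {
  list(
    pains = compile_catalog(
      system.file("extdata", "pains_catalog.tsv", package = "mtscreen",
                  mustWork = TRUE), name = "pains"),
    schiff_base = compile_catalog(
      system.file("extdata", "schiff_catalog.tsv", package = "mtscreen",
                  mustWork = TRUE), name = "schiff_base"))
}

# Match every catalog pattern against a set of SMILES.
# Returns data.frame(compound_id, catalog, pattern_id); unparseable
# structures come back with catalog = "unevaluable".
match_alerts <- function(compound_id, smiles, catalogs) {
  stopifnot(length(compound_id) == length(smiles))
  if (inherits(catalogs, "alert_catalog")) catalogs <- list(catalogs)
  empty <- data.frame(compound_id = character(), catalog = character(),
                      pattern_id = character(), stringsAsFactors = FALSE)
  if (!length(compound_id)) return(empty)
  ok <- is_valid_smiles(smiles)
  alerts <- list(empty)
  if (any(!ok))
    alerts[[length(alerts) + 1L]] <- data.frame(
      compound_id = compound_id[!ok], catalog = "unevaluable",
      pattern_id = "parse_failure", stringsAsFactors = FALSE)
  if (any(ok)) {
    sdf <- suppressWarnings(
      ChemmineR::smiles2sdf(stats::setNames(smiles[ok],
                                            paste0("m", seq_len(sum(ok))))))
    for (cat in catalogs) {
      for (i in seq_len(nrow(cat$patterns))) {
        n <- ChemmineR::smartsSearchOB(sdf, cat$patterns$smarts[i],
                                       uniqueMatches = FALSE)
        hit <- which(n > 0)
        if (length(hit))
          alerts[[length(alerts) + 1L]] <- data.frame(
            compound_id = compound_id[ok][hit], catalog = cat$name,
            pattern_id = cat$patterns$pattern_id[i],
            stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, alerts)
  rownames(out) <- NULL
  out
}

#' Flag one molecule against alert catalogs
#'
#' @param record a single-row `molecule_library`, or a SMILES string.
#' @param catalogs an `alert_catalog` or list of them (default: the
#'   bundled PAINS + Schiff-base catalogs).
#' @return data.frame of alerts (`catalog`, `pattern_id`); zero rows means
#'   clean. An unparseable structure yields a single `unevaluable` alert
#'   (treated as removed by [filter_clean()], conservatively).
#' @examples
#' flag_molecule("O=C1CSC(=S)N1")  # rhodanine: PAINS alert
#' flag_molecule("CCO")            # clean
#' @export
flag_molecule <- function(record, catalogs = default_catalogs()) {
  smi <- if (is.data.frame(record)) record$smiles[1L] else record
  id <- if (is.data.frame(record)) record$compound_id[1L] else "query"
  out <- match_alerts(id, smi, catalogs)
  out[, c("catalog", "pattern_id"), drop = FALSE]
}

#' Remove compounds matching substructure alerts
#'
#' Survivors are exactly the records with zero alerts across all supplied
#' catalogs; removed compounds are logged once per matched pattern.
#' Unparseable structures are removed as `unevaluable` rather than passed
#' (the stage exists to protect downstream assays). Survivors and removed
#' compounds always partition the input, and adding patterns can only
#' shrink the survivor set.
#'
#' @param records a `molecule_library` data.frame.
#' @param catalogs an `alert_catalog` or list of them.
#' @return list with `kept` (surviving records), `removed` (data.frame:
#'   compound_id, catalog, pattern_id).
#' @export
filter_clean <- function(records, catalogs = default_catalogs()) {
  stopifnot(is.data.frame(records))
  alerts <- match_alerts(records$compound_id, records$smiles, catalogs)
  bad <- records$compound_id %in% alerts$compound_id
  list(kept = records[!bad, , drop = FALSE], removed = alerts)
}
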