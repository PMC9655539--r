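#' Point affinity from a predicted affinity range
#'
#' Predicted affinities arrive as a (lower, upper) Ki range in nM; the
#' point estimate is the geometric mean of the two boundaries,
#' `sqrt(lower * upper)`, which lies between them and is exact when the
#' range is symmetric on the log scale around the true value.
#'
#' @param ki_lower_nM,ki_upper_nM numeric vectors of range bounds in nM;
#'   requires `0 < lower <= upper` elementwise.
#' @return numeric vector of point Ki estimates in nM.
#' @examples
#' ki_from_range(1, 100)  # 10
#' @export
ki_from_range <- function(ki_lower_nM, ki_upper_nM) {
  stopifnot(is.numeric(ki_lower_nM), is.numeric(ki_upper_nM))
  bad <- !is.na(ki_lower_nM) & !is.na(ki_upper_nM) &
    (ki_lower_nM <= 0 | ki_lower_nM > ki_upper_nM)
  if (any(bad))
    stopf("invalid affinity range(s): need 0 < lower <= upper (%d row(s))",
          sum(bad))
  sqrt(ki_lower_nM * ki_upper_nM)
}

#' Ki multiplication product: the multi-target ranking statistic
#'
#' The rank-fusion statistic for simultaneous activity: the plain product
#' of a compound's predicted Ki values (nM) across the targets, in nM^3
#' for a three-target panel. Lower is better. Using a product rather than
#' a sum makes the ranking invariant to per-target rescaling (multiplying
#' any one target's affinities by a constant shifts every product by the
#' same factor), so differently-scaled scoring functions cannot distort
#' the order. No rescaling is applied; presentation rounds to 4
#' significant figures ([format_product()]).
#'
#' @param ki numeric vector of per-target Ki values in nM (all positive,
#'   no missing values), e.g. `c(AChE = 3.808, HDAC2 = 1615, MAOB = 1.784)`.
#' @return the product, in nM^`length(ki)`.
#' @export
product_statistic <- function(ki) {
  if (anyNA(ki)) stopf("missing Ki: product undefined, compound cannot be ranked")
  stopifnot(is.numeric(ki), length(ki) >= 1L)
  if (any(ki <= 0)) stopf("Ki values must be positive")
  prod(ki)
}

#' @rdname product_statistic
#' @param x products to format.
#' @return `format_product()`: `x` rounded to 4 significant figures.
#' @export
format_product <- function(x) signif(x, 4)

# long (compound_id, target, ki_nM) -> wide matrix-like data.frame with
# one Ki column per target plus the product; compounds missing any target
# get NA product.
ki_wide <- function(affinities, targets = NULL) {
  stopifnot(all(c("compound_id", "target", "ki_nM") %in% names(affinities)))
  if (is.null(targets)) targets <- unique(affinities$target)
  ids <- unique(affinities$compound_id)
  kmat <- matrix(NA_real_, length(ids), length(targets),
                 dimnames = list(ids, targets))
  sub <- affinities[affinities$target %in% targets, , drop = FALSE]
  kmat[cbind(match(sub$compound_id, ids), match(sub$target, targets))] <-
    sub$ki_nM
  out <- data.frame(compound_id = ids, kmat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$product <- apply(kmat, 1L, function(r)
    if (anyNA(r) || any(r <= 0)) NA_real_ else prod(r))
  out
}

#' Per-target and product affinity gate
#'
#' A compound survives iff its predicted Ki is strictly below
#' `per_target_max` on every target \emph{and} the Ki multiplication
#' product is strictly below `product_max`. Defaults encode the hit-level
#' constraints of the cascade: 5.0 uM per enzyme and 100e6 nM^3 for the
#' product. Compounds missing a Ki for any target cannot be evaluated and
#' are removed with reason `missing_ki` (logged, never silent).
#'
#' @param affinities long data.frame (`compound_id`, `target`, `ki_nM`) or
#'   a wide data.frame from `rank_by_product()`-compatible input with one
#'   column per target.
#' @param per_target_max per-enzyme Ki ceiling in nM (strict).
#' @param product_max product ceiling in nM^3 (strict).
#' @param targets targets required; default all targets present.
#' @return list with `kept` (surviving compound ids, input order),
#'   `removed` (data.frame: compound_id, reason), and `ki` (wide Ki table
#'   of survivors, with `product`).
#' @export
affinity_gate <- function(affinities, per_target_max = 5000,
                          product_max = 1e8, targets = NULL) {
  wide <- ki_wide(affinities, targets = targets)
  tcols <- setdiff(names(wide), c("compound_id", "product"))
  kmat <- as.matrix(wide[, tcols, drop = FALSE])
  missing_ki <- rowSums(is.na(kmat)) > 0L
  pass_target <- !missing_ki & rowSums(kmat < per_target_max) == ncol(kmat)
  pass <- pass_target & !is.na(wide$product) & wide$product < product_max

  reason <- rep(NA_character_, nrow(wide))
  reason[missing_ki] <- "missing_ki"
  reason[!missing_ki & !pass_target] <- "ki_above_per_target_max"
  reason[!missing_ki & pass_target & !pass] <- "product_above_max"
  removed <- data.frame(compound_id = wide$compound_id[!pass],
                        reason = reason[!pass], stringsAsFactors = FALSE)
  list(kept = wide$compound_id[pass], removed = removed,
       ki = wide[pass, , drop = FALSE])
}

#' Rank compounds by the Ki multiplication product
#'
#' Orders compounds ascending by the full-precision product of their
#' per-target Ki values (lower product = better simultaneous affinity).
#' Ties are broken by `compound_id`, so the ranking is stable and
#' independent of input order. Ranks are `1..n` without gaps. The
#' `product_4sf` column carries the presentation value rounded to 4
#' significant figures.
#'
#' @param affinities long data.frame (`compound_id`, `target`, `ki_nM`),
#'   or the `ki` component returned by [affinity_gate()].
#' @param targets targets to use; default all present.
#' @return data.frame: `rank`, `compound_id`, one Ki column per target,
#'   `product`, `product_4sf`.
#' @examples
#' fx <- hit_fixture()
#' head(rank_by_product(fx$affinities), 3)
#' @export
rank_by_product <- function(affinities, targets = NULL) {
  wide <- if (all(c("compound_id", "product") %in% names(affinities)))
    affinities else ki_wide(affinities, targets = targets)
  if (anyNA(wide$product))
    stopf("missing Ki for %d compound(s): product undefined, cannot rank",
          sum(is.na(wide$product)))
  ord <- order(wide$product, wide$compound_id)
  out <- wide[ord, , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(out)), out, check.names = FALSE,
                    stringsAsFactors = FALSE)
  out$product_4sf <- format_product(out$product)
  rownames(out) <- NULL
  out
}
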