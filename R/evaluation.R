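#' Evaluate selected SNPs against a known-positive list
#'
#' Sensitivity is hits over positives, precision hits over selected, and
#' the over-representation probability is the upper-tail hypergeometric
#' P(X >= hits) for drawing that many positives in `|selected|` draws
#' without replacement from the universe.
#'
#' @param selected character vector of selected SNP ids (subset of
#'   `universe`).
#' @param positives character vector of known-positive SNP ids (subset of
#'   `universe`).
#' @param universe character vector of all evaluable SNP ids.
#' @param typeMap optional data.frame with columns `snp_id`, `site_type`
#'   for the per-site-type breakdown (a SNP with several types counts once
#'   per type).
#' @return list with `n_universe`, `n_positives`, `n_selected`, `n_hits`,
#'   `sensitivity`, `precision` (NA and `flagged = TRUE` when nothing was
#'   selected), `hyper_p`, and `per_type` (data.frame from
#'   [perTypePrecision()] when `typeMap` is given).
#' @export
evaluateCandidates <- function(selected, positives, universe,
                               typeMap = NULL) {
  universe <- unique(universe)
  selected <- unique(selected)
  positives <- unique(positives)
  if (!all(selected %in% universe) || !all(positives %in% universe))
    stop("selected and positives must be subsets of the universe")
  hits <- intersect(selected, positives)
  nU <- length(universe); nP <- length(positives)
  nS <- length(selected); nH <- length(hits)
  flagged <- nS == 0L
  out <- list(
    n_universe = nU, n_positives = nP, n_selected = nS, n_hits = nH,
    sensitivity = if (nP > 0L) nH / nP else NA_real_,
    precision = if (flagged) NA_real_ else nH / nS,
    hyper_p = if (flagged) 1 else
      stats::phyper(nH - 1L, nP, nU - nP, nS, lower.tail = FALSE),
    flagged = flagged)
  if (!is.null(typeMap))
    out$per_type <- perTypePrecision(selected, positives, typeMap)
  out
}

#' Per-site-type precision of the positive SNPs
#'
#' For each site type, the fraction of known-positive SNPs carrying that
#' type that were selected. Types with no positive SNP are omitted.
#'
#' @param selected character vector of selected SNP ids.
#' @param positives character vector of known-positive SNP ids.
#' @param typeMap data.frame with columns `snp_id`, `site_type`.
#' @return data.frame with columns `site_type`, `hits`, `total`,
#'   `precision`.
#' @export
perTypePrecision <- function(selected, positives, typeMap) {
  tm <- unique(typeMap[typeMap$snp_id %in% positives, , drop = FALSE])
  if (nrow(tm) == 0L)
    return(data.frame(site_type = character(0), hits = integer(0),
                      total = integer(0), precision = numeric(0),
                      stringsAsFactors = FALSE))
  sp <- split(tm$snp_id, tm$site_type)
  out <- data.frame(
    site_type = names(sp),
    hits = vapply(sp, function(x) length(intersect(x, selected)),
                  integer(1L)),
    total = vapply(sp, length, integer(1L)),
    stringsAsFactors = FALSE)
  out$precision <- out$hits / out$total
  out <- out[order(out$site_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}
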