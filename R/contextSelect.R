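## Biological-context candidate selection: GO enrichment of the host genes
## of nominally significant seed-site SNPs, overlap with the enrichment of
## known disease genes, and emission of the SNPs that satisfy both the
## p-value threshold and the shared biological context.

#' Hypergeometric GO-term enrichment
#'
#' For each term annotated to at least one query gene, computes the
#' upper-tail hypergeometric probability of drawing `k` or more annotated
#' genes in a query of size `n` from a background of size `N` containing
#' `K` annotated genes. P-values are raw (uncorrected); set
#' `correct = "BH"` for Benjamini-Hochberg adjusted values in an extra
#' column.
#'
#' @param queryGenes character vector (must be a subset of
#'   `backgroundGenes`).
#' @param annotations data.frame with columns `gene`, `term`.
#' @param backgroundGenes character vector defining the gene universe.
#' @param pThreshold enrichment cutoff for the `enriched` flag (default
#'   0.05).
#' @param correct `"none"` (default) or `"BH"`.
#' @return data.frame with columns `term`, `k`, `K`, `n`, `N`, `p`,
#'   `enriched` (and `p_adj` when correcting).
#' @export
goEnrich <- function(queryGenes, annotations, backgroundGenes,
                     pThreshold = 0.05, correct = c("none", "BH")) {
  correct <- match.arg(correct)
  queryGenes <- unique(queryGenes)
  backgroundGenes <- unique(backgroundGenes)
  if (!all(queryGenes %in% backgroundGenes))
    stop("query genes must be a subset of the background")
  if (length(queryGenes) == 0L) {
    warning("empty query gene set")
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE))
  }
  ann <- annotations[annotations$gene %in% backgroundGenes, , drop = FALSE]
  ann <- unique(ann[, c("gene", "term")])
  N <- length(backgroundGenes)
  n <- length(queryGenes)
  K_all <- table(ann$term)
  in_query <- ann[ann$gene %in% queryGenes, , drop = FALSE]
  k_all <- table(in_query$term)
  terms <- names(k_all)              # only terms with k >= 1 reported
  if (length(terms) == 0L)
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      enriched = logical(0), stringsAsFactors = FALSE))
  k <- as.integer(k_all[terms])
  K <- as.integer(K_all[terms])
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N, p = p,
                    enriched = p <= pThreshold, stringsAsFactors = FALSE)
  if (correct == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$enriched <- out$p_adj <= pThreshold
  }
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Overlap test between two enriched-term lists
#'
#' Lays the two term sets over a common term universe as a 2x2 table
#' (in both / query only / disease only / neither) and computes the
#' one-sided Fisher exact p-value for over-representation of the overlap.
#'
#' @param queryTerms,diseaseTerms character vectors of enriched terms,
#'   both subsets of `universe`.
#' @param universe character vector of all testable terms.
#' @return list with `overlap` (character vector), `table` (2x2 matrix)
#'   and `fisher_p`.
#' @export
overlapTest <- function(queryTerms, diseaseTerms, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty term universe")
  queryTerms <- unique(queryTerms)
  diseaseTerms <- unique(diseaseTerms)
  if (!all(queryTerms %in% universe) || !all(diseaseTerms %in% universe))
    stop("term sets must be subsets of the universe")
  both <- intersect(queryTerms, diseaseTerms)
  tab <- matrix(c(length(both),
                  length(queryTerms) - length(both),
                  length(diseaseTerms) - length(both),
                  length(universe) - length(union(queryTerms, diseaseTerms))),
                nrow = 2L,
                dimnames = list(c("in_query", "not_query"),
                                c("in_disease", "not_disease")))
  fp <- stats::fisher.test(tab, alternative = "greater")$p.value
  list(overlap = sort(both), table = tab, fisher_p = fp)
}

#' Select candidate causal seed-site SNPs
#'
#' A SNP is a candidate when its inherited GWAS p-value is at or below
#' `pSnp` and at least one of its host genes is annotated to a term in
#' `overlapTerms` (the biological context shared between the significant
#' SNPs' host genes and the known disease genes).
#'
#' @param assignments output of [assignPvalues()].
#' @param snpGenes data.frame with columns `snp_id`, `gene_symbol` (host
#'   genes via the transcripts whose 3'UTRs contain the SNP).
#' @param overlapTerms character vector of overlap terms.
#' @param annotations data.frame with columns `gene`, `term`.
#' @param pSnp SNP p-value threshold (default 0.01).
#' @return data.frame with columns `snp_id`, `dataset`, `gene_symbol`,
#'   `inherited_p`, `terms` (comma-joined overlap terms supporting the
#'   call), one row per (SNP, host gene).
#' @export
selectCandidates <- function(assignments, snpGenes, overlapTerms,
                             annotations, pSnp = 0.01) {
  sig <- assignments[assignments$inherited_p <= pSnp, , drop = FALSE]
  ann <- annotations[annotations$term %in% overlapTerms, , drop = FALSE]
  empty <- data.frame(snp_id = character(0), dataset = character(0),
                      gene_symbol = character(0), inherited_p = numeric(0),
                      terms = character(0), stringsAsFactors = FALSE)
  if (nrow(sig) == 0L || nrow(ann) == 0L) return(empty)
  hg <- unique(snpGenes[snpGenes$gene_symbol %in% ann$gene, , drop = FALSE])
  m <- merge(sig, hg, by = "snp_id")
  if (nrow(m) == 0L) return(empty)
  term_of <- tapply(ann$term, ann$gene, function(x)
    paste(sort(unique(x)), collapse = ","))
  out <- data.frame(snp_id = m$snp_id, dataset = m$dataset,
                    gene_symbol = m$gene_symbol,
                    inherited_p = m$inherited_p,
                    terms = unname(term_of[m$gene_symbol]),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$dataset, out$snp_id, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the whole context-selection step for one GWAS dataset
#'
#' Convenience wrapper: hosts of SNPs at `p <= pSnp` are GO-enriched, the
#' disease gene list is GO-enriched on the same background, the two
#' enriched-term lists are overlap-tested, and candidates are emitted.
#'
#' @inheritParams selectCandidates
#' @param diseaseGenes character vector of disease-related genes for the
#'   dataset.
#' @param backgroundGenes gene universe for both enrichments.
#' @param pGo term-enrichment threshold (default 0.05).
#' @param termUniverse term universe for the overlap test; default all
#'   terms annotated to at least one background gene.
#' @return list with `query_enrich`, `disease_enrich` (data.frames),
#'   `overlap` (list from [overlapTest()]) and `candidates` (data.frame).
#' @export
contextSelect <- function(assignments, snpGenes, diseaseGenes, annotations,
                          backgroundGenes, pSnp = 0.01, pGo = 0.05,
                          termUniverse = NULL) {
  sig <- assignments[assignments$inherited_p <= pSnp, , drop = FALSE]
  hosts <- unique(snpGenes$gene_symbol[snpGenes$snp_id %in% sig$snp_id])
  hosts <- intersect(hosts, backgroundGenes)
  diseaseGenes <- intersect(unique(diseaseGenes), backgroundGenes)
  qe <- goEnrich(hosts, annotations, backgroundGenes, pThreshold = pGo)
  de <- goEnrich(diseaseGenes, annotations, backgroundGenes,
                 pThreshold = pGo)
  if (is.null(termUniverse)) {
    ann <- annotations[annotations$gene %in% backgroundGenes, , drop = FALSE]
    termUniverse <- unique(ann$term)
  }
  ov <- overlapTest(qe$term[qe$enriched], de$term[de$enriched],
                    termUniverse)
  cand <- selectCandidates(assignments, snpGenes, ov$overlap, annotations,
                           pSnp = pSnp)
  list(query_enrich = qe, disease_enrich = de, overlap = ov,
       candidates = cand)
}
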