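#' Build microRNA-gene-disease trilateral interactions
#'
#' A validated microRNA-gene interaction is promoted to a trilateral
#' interaction for every disease that is linked to both the microRNA and
#' the gene in their respective tables. Disease names are matched exactly
#' after case-folding and trimming (optionally through a synonym map).
#'
#' @param mirnaGene data.frame with columns `mirna_id`, `gene`.
#' @param mirnaDisease data.frame with columns `mirna_id`, `disease`.
#' @param geneDisease data.frame with columns `gene`, `disease`.
#' @param synonyms optional named character vector mapping disease
#'   synonyms to canonical names.
#' @return data.frame with columns `mirna_id`, `gene`, `disease`,
#'   deduplicated and deterministically ordered.
#' @export
buildTrilateral <- function(mirnaGene, mirnaDisease, geneDisease,
                            synonyms = NULL) {
  norm <- function(x) {
    x <- tolower(trimws(x))
    if (!is.null(synonyms)) {
      hit <- x %in% names(synonyms)
      x[hit] <- unname(synonyms[x[hit]])
    }
    x
  }
  md <- unique(data.frame(mirna_id = mirnaDisease$mirna_id,
                          disease = norm(mirnaDisease$disease),
                          stringsAsFactors = FALSE))
  gd <- unique(data.frame(gene = geneDisease$gene,
                          disease = norm(geneDisease$disease),
                          stringsAsFactors = FALSE))
  mg <- unique(mirnaGene[, c("mirna_id", "gene")])
  x <- merge(mg, md, by = "mirna_id")
  x <- merge(x, gd, by = c("gene", "disease"))
  out <- unique(x[, c("mirna_id", "gene", "disease")])
  out <- out[order(out$mirna_id, out$gene, out$disease), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SNPs able to perturb disease-associated interactions
#'
#' Flags every SNP with a create/loss effect touching a (microRNA, gene)
#' pair that appears in at least one trilateral interaction, and annotates
#' it with all diseases of the touched triples.
#'
#' @param interactions data.frame from [buildTrilateral()].
#' @param effects allelic-effect data.frame (columns `snp_id`,
#'   `gene_symbol`, `mirnas`).
#' @return data.frame with columns `snp_id`, `diseases` (comma-joined),
#'   one row per SNP.
#' @export
snpsPerturbing <- function(interactions, effects) {
  empty <- data.frame(snp_id = character(0), diseases = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(effects) == 0L || nrow(interactions) == 0L) return(empty)
  m <- strsplit(effects$mirnas, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(effects)), lengths(m))
  pairs <- data.frame(snp_id = effects$snp_id[idx],
                      gene = effects$gene_symbol[idx],
                      mirna_id = unlist(m), stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  hit <- merge(pairs, interactions, by = c("mirna_id", "gene"))
  if (nrow(hit) == 0L) return(empty)
  ds <- tapply(hit$disease, hit$snp_id, function(x)
    paste(sort(unique(x)), collapse = ","))
  out <- data.frame(snp_id = names(ds), diseases = unname(ds),
                    stringsAsFactors = FALSE)
  out <- out[order(out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
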