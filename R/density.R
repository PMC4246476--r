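#' Classify a SNP's minor allele frequency
#'
#' SNPs with fewer than `minChromosomes` observed chromosomes cannot
#' estimate MAF reliably and are classed `unknown`, as are SNPs with no
#' MAF at all; otherwise MAF at or above `commonThreshold` is `common`,
#' below it `rare`.
#'
#' @param maf numeric vector of minor allele frequencies (NA allowed).
#' @param nChromosomes integer vector of observed chromosome counts.
#' @param commonThreshold MAF cutoff for common SNPs (default 0.01).
#' @param minChromosomes minimum chromosomes for a usable MAF (default
#'   100).
#' @return character vector in `c("common", "rare", "unknown")`.
#' @export
#' @examples
#' classifyMaf(c(0.05, 0.005, 0.3), c(2000L, 120L, 80L))
classifyMaf <- function(maf, nChromosomes, commonThreshold = 0.01,
                        minChromosomes = 100L) {
  out <- rep("unknown", length(maf))
  usable <- !is.na(maf) & !is.na(nChromosomes) &
    nChromosomes >= minChromosomes
  out[usable & maf >= commonThreshold] <- "common"
  out[usable & maf < commonThreshold] <- "rare"
  out
}

.regionRanges <- function(df) {
  GenomicRanges::reduce(GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(df$start, df$end)))
}

#' SNP density per mRNA region class, split by MAF class
#'
#' Counts each SNP in every region class whose merged genomic footprint
#' contains it (so a SNP inside a seed site contributes to both the MRESS
#' and the 3UTR rows) and divides by the merged footprint length in
#' kilobases. Overlapping intervals within a class are merged first so no
#' base is double-counted.
#'
#' @param snps SNP data.frame (needs `chrom`, `pos`, `maf`,
#'   `n_chromosomes`).
#' @param regions region-table data.frame.
#' @param mressRegions data.frame of genomic seed-site intervals with
#'   columns `chrom`, `start`, `end` (1-based inclusive); see
#'   [sitesToGenomic()].
#' @param commonThreshold,minChromosomes passed to [classifyMaf()].
#' @return data.frame with one row per (region, maf_class): `snp_count`,
#'   `total_kb`, `density` (SNPs per kb; NA with a `flagged` marker when a
#'   region class is empty).
#' @export
regionDensity <- function(snps, regions, mressRegions,
                          commonThreshold = 0.01, minChromosomes = 100L) {
  cls <- classifyMaf(snps$maf, snps$n_chromosomes, commonThreshold,
                     minChromosomes)
  sp <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(snps$pos, snps$pos))
  region_sets <- list(
    `5UTR` = regions[regions$region_type == "5UTR", , drop = FALSE],
    CDS = regions[regions$region_type == "CDS", , drop = FALSE],
    `3UTR` = regions[regions$region_type == "3UTR", , drop = FALSE],
    MRESS = mressRegions)
  out <- list()
  for (rn in names(region_sets)) {
    df <- region_sets[[rn]]
    if (is.null(df) || nrow(df) == 0L) {
      out[[length(out) + 1L]] <- data.frame(
        region = rn, maf_class = c("common", "rare", "unknown"),
        snp_count = NA_integer_, total_kb = NA_real_, density = NA_real_,
        flagged = TRUE, stringsAsFactors = FALSE)
      next
    }
    gr <- .regionRanges(df)
    kb <- sum(GenomicRanges::width(gr)) / 1000
    inside <- GenomicRanges::countOverlaps(sp, gr) > 0L
    for (mc in c("common", "rare", "unknown")) {
      cnt <- sum(inside & cls == mc)
      out[[length(out) + 1L]] <- data.frame(
        region = rn, maf_class = mc, snp_count = cnt, total_kb = kb,
        density = cnt / kb, flagged = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Project UTR-offset seed sites onto genomic coordinates
#'
#' Maps each site's 0-based half-open UTR footprint back through the
#' transcript's (possibly spliced, possibly minus-strand) 3'UTR blocks.
#'
#' @param sites site data.frame from [scanSites()].
#' @param regions region-table data.frame.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive genomic intervals, one or more per site).
#' @export
sitesToGenomic <- function(sites, regions) {
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) return(empty)
  u3 <- regions[regions$region_type == "3UTR", , drop = FALSE]
  if (nrow(u3) == 0L) return(empty)
  ## per-block sense-space offsets, vectorized over a sites x blocks join
  u3 <- u3[order(u3$transcript_id, u3$start), , drop = FALSE]
  w <- u3$end - u3$start + 1L
  cumplus <- stats::ave(w, u3$transcript_id, FUN = function(x)
    cumsum(x) - x)
  cumminus <- stats::ave(w, u3$transcript_id, FUN = function(x)
    rev(cumsum(rev(x)) - rev(x)))
  blocks <- data.frame(transcript_id = u3$transcript_id, chrom = u3$chrom,
                       strand = u3$strand, bstart = u3$start,
                       bend = u3$end, w = w,
                       cum = ifelse(u3$strand == "-", cumminus, cumplus),
                       stringsAsFactors = FALSE)
  j <- merge(sites[, c("transcript_id", "start", "end")], blocks,
             by = "transcript_id")
  lo <- pmax(j$start, j$cum)
  hi <- pmin(j$end, j$cum + j$w)
  keep <- lo < hi
  j <- j[keep, , drop = FALSE]; lo <- lo[keep]; hi <- hi[keep]
  plus <- j$strand == "+"
  gs <- ifelse(plus, j$bstart + (lo - j$cum), j$bend - (hi - 1L - j$cum))
  ge <- ifelse(plus, j$bstart + (hi - 1L - j$cum), j$bend - (lo - j$cum))
  res <- data.frame(chrom = j$chrom, start = as.integer(gs),
                    end = as.integer(ge), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
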