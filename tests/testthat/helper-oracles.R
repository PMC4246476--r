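## Independent oracles and fixture builders used across the test files.
## Everything here is written from the duplex/statistics definitions
## directly, avoiding the package's own scanning and tail-probability
## code paths.

.cmp <- c(A = "U", C = "G", G = "C", U = "A")

## reverse complement built by explicit per-base complement + reversal
oracleRc <- function(x) {
  paste(rev(.cmp[strsplit(x, "")[[1L]]]), collapse = "")
}

## exhaustive substring enumeration of all rc(seed)-derived patterns,
## one record per (transcript, interval, type, microRNA)
oracleScan <- function(utrs, mirnas) {
  recs <- list()
  for (tx in names(utrs)) {
    u <- utrs[[tx]]
    n <- nchar(u)
    if (n < 7L) next
    win <- substring(u, 1:(n - 6L), 7:n)      # all 7-nt windows
    for (mid in names(mirnas)) {
      m <- mirnas[[mid]]
      if (nchar(m) < 8L) next
      for (kind in c("1-7", "2-8")) {
        seed <- if (kind == "1-7") substr(m, 1L, 7L) else substr(m, 2L, 8L)
        pat <- oracleRc(seed)
        hits <- which(win == pat) - 1L        # 0-based starts
        for (s in hits) {
          if (kind == "1-7") {
            extra <- .cmp[[substr(m, 8L, 8L)]]
            if (s >= 1L && substr(u, s, s) == extra)
              recs[[length(recs) + 1L]] <- c(tx, s - 1L, s + 7L, "8mer", mid)
            else
              recs[[length(recs) + 1L]] <- c(tx, s, s + 7L, "7mer(1-7)", mid)
          } else {
            extra <- .cmp[[substr(m, 1L, 1L)]]
            nb <- if (s + 7L < n) substr(u, s + 8L, s + 8L) else NA
            if (!is.na(nb) && nb == extra)
              recs[[length(recs) + 1L]] <- c(tx, s, s + 8L, "8mer", mid)
            else if (!is.na(nb) && nb == "A")
              recs[[length(recs) + 1L]] <- c(tx, s, s + 8L, "8mer-1a", mid)
            else
              recs[[length(recs) + 1L]] <- c(tx, s, s + 7L, "7mer(2-8)", mid)
          }
        }
      }
    }
  }
  if (!length(recs))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), site_type = character(0),
                      mirna_id = character(0), stringsAsFactors = FALSE))
  m <- do.call(rbind, recs)
  out <- unique(data.frame(transcript_id = m[, 1L],
                           start = as.integer(m[, 2L]),
                           end = as.integer(m[, 3L]), site_type = m[, 4L],
                           mirna_id = m[, 5L], stringsAsFactors = FALSE))
  out <- out[order(out$transcript_id, out$start, out$site_type,
                   out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## explode a scanSites() data.frame to member-level records comparable
## with oracleScan()
explodeSites <- function(sites) {
  if (nrow(sites) == 0L)
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), site_type = character(0),
                      mirna_id = character(0), stringsAsFactors = FALSE))
  m <- strsplit(sites$mirnas, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(sites)), lengths(m))
  out <- data.frame(transcript_id = sites$transcript_id[idx],
                    start = sites$start[idx], end = sites$end[idx],
                    site_type = sites$site_type[idx],
                    mirna_id = unlist(m), stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$transcript_id, out$start, out$site_type,
                   out$mirna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## exact upper-tail hypergeometric P(X >= k) by enumeration of all
## n-subsets of a universe of size N with K marked elements (N <= 12)
oracleHyperGe <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(subsets, 2L, function(s) sum(s %in% marked))
  mean(hits >= k)
}

randomRna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

## write a minimal reference trio (3'UTR FASTA + region TSV + SNP TSV)
## into dir and return the three paths
writeTinyReference <- function(dir, utrs, regions, snps) {
  fa <- file.path(dir, "utr3.fa")
  writeLines(unlist(lapply(names(utrs), function(n)
    c(paste0(">", n), utrs[[n]]))), fa)
  rg <- file.path(dir, "regions.tsv")
  utils::write.table(regions, rg, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sn <- file.path(dir, "snps.tsv")
  utils::write.table(snps, sn, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(fasta = fa, regions = rg, snps = sn)
}

## single-transcript region table on the plus strand
tinyRegions <- function(tx = "NM_000001", gene = "GENE1", utr3len = 60L) {
  data.frame(transcript_id = tx, gene_symbol = gene, chrom = "chr1",
             strand = "+", region_type = c("5UTR", "CDS", "3UTR"),
             start = c(1L, 101L, 1001L),
             end = c(100L, 1000L, 1000L + utr3len),
             stringsAsFactors = FALSE)
}

tinySnps <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(snp_id = r[[1L]], chrom = r[[2L]], pos = as.integer(r[[3L]]),
               ref_allele = r[[4L]], alt_allele = r[[5L]],
               maf = as.numeric(r[[6L]]),
               n_chromosomes = as.integer(r[[7L]]),
               stringsAsFactors = FALSE)))
}
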