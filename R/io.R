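## File formats
##
## Everything on disk is plain text: FASTA for sequences, TSV for tables.
## All coordinates in files are 1-based inclusive; in memory they are
## 0-based half-open (see toInternalCoords).

#' Read a mature microRNA FASTA file
#'
#' Sequences are normalized to uppercase RNA (T becomes U).
#'
#' @param path FASTA file of mature microRNA sequences.
#' @return named character vector of RNA sequences.
#' @export
readMirnaFasta <- function(path) {
  x <- .readFastaNormalized(path)
  .checkRna(x, sprintf("microRNA FASTA %s", basename(path)))
  x
}

#' Read an mRNA-region FASTA file (3'UTR, 5'UTR or CDS)
#'
#' Sequence names must be transcript accessions matching the region table.
#' Sequences are normalized to uppercase RNA in 5'-to-3' sense orientation.
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
readUtrFasta <- function(path) {
  x <- .readFastaNormalized(path)
  .checkRna(x, sprintf("FASTA %s", basename(path)))
  x
}

.readFastaNormalized <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e)
                    stop(sprintf("cannot parse FASTA '%s': %s",
                                 path, conditionMessage(e))))
  x <- .normalizeRna(as.character(set))
  ## keep only the first whitespace-delimited token of each header
  names(x) <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1L), 1L)
  if (any(!nzchar(names(x))))
    stop(sprintf("malformed FASTA header (empty id) in '%s'", path))
  x
}

#' Read the transcript region table
#'
#' A 7-column TSV (`transcript_id`, `gene_symbol`, `chrom`, `strand`,
#' `region_type`, `start`, `end`) giving genomic coordinates (1-based
#' inclusive) of every 5'UTR, CDS and 3'UTR block of each transcript.
#'
#' @param path TSV file with a header line.
#' @return data.frame with the seven columns; coordinates kept 1-based
#'   (genomic positions are only ever compared, never used as string
#'   offsets).
#' @export
readRegionTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stopifnotCols(df, c("transcript_id", "gene_symbol", "chrom", "strand",
                       "region_type", "start", "end"), "region table")
  if (!all(df$strand %in% c("+", "-")))
    stop("region table strand must be '+' or '-'")
  if (!all(df$region_type %in% c("5UTR", "CDS", "3UTR")))
    stop("region_type must be one of 5UTR, CDS, 3UTR")
  if (any(df$end < df$start))
    stop("region table has end < start")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Read the SNP table
#'
#' TSV with columns `snp_id`, `chrom`, `pos` (1-based), `ref_allele`,
#' `alt_allele`, `maf` (may be NA), `n_chromosomes`. Alleles are single
#' bases on the forward genomic strand. Rows that are not bi-allelic
#' single-nucleotide variants are rejected and counted in the attached
#' load report (`attr(x, "report")`).
#'
#' @param path TSV file with a header line.
#' @return data.frame of accepted SNPs with attribute `report`, a named
#'   integer vector of rejection counts.
#' @export
readSnpTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  .stopifnotCols(df, c("snp_id", "chrom", "pos", "ref_allele", "alt_allele",
                       "maf", "n_chromosomes"), "SNP table")
  df$pos <- as.integer(df$pos)
  df$maf <- as.numeric(df$maf)
  df$n_chromosomes <- as.integer(df$n_chromosomes)
  ok_base <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  multi <- grepl("/", df$ref_allele) | grepl("/", df$alt_allele) |
    nchar(df$ref_allele) > 1L | nchar(df$alt_allele) > 1L
  bad <- !multi & (!ok_base(df$ref_allele) | !ok_base(df$alt_allele) |
                     df$ref_allele == df$alt_allele)
  bad_maf <- !multi & !bad & !is.na(df$maf) & (df$maf < 0 | df$maf > 0.5)
  keep <- !(multi | bad | bad_maf)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- c(multi_allelic = sum(multi),
                           bad_allele = sum(bad),
                           bad_maf = sum(bad_maf))
  out
}

#' Load the sequence + region + SNP reference bundle
#'
#' Joins the 3'UTR FASTA with the region table, checks that the sequence
#' length matches the summed 3'UTR region lengths, drops transcripts whose
#' 3'UTR is shorter than `minUtrLen` (microRNA targeting of very short
#' UTRs is improbable), and reads the SNP table.
#'
#' @param utr3Fasta path to the 3'UTR FASTA (sense orientation).
#' @param regionPath path to the region table TSV.
#' @param snpPath path to the SNP table TSV.
#' @param minUtrLen minimum retained 3'UTR length (default 50).
#' @return list with `transcripts` (data.frame: transcript_id, gene_symbol,
#'   chrom, strand, utr3), `regions` (region table data.frame), `snps`
#'   (SNP data.frame) and `report` (named integer vector of dropped-record
#'   counts).
#' @export
loadReference <- function(utr3Fasta, regionPath, snpPath, minUtrLen = 50L) {
  utr3 <- readUtrFasta(utr3Fasta)
  regions <- readRegionTable(regionPath)
  snps <- readSnpTable(snpPath)
  report <- attr(snps, "report")

  tx <- unique(regions[, c("transcript_id", "gene_symbol", "chrom", "strand")])
  if (anyDuplicated(tx$transcript_id))
    stop("inconsistent gene/chrom/strand within a transcript in region table")
  no_seq <- !(tx$transcript_id %in% names(utr3))
  report <- c(report, no_utr3_seq = sum(no_seq))
  tx <- tx[!no_seq, , drop = FALSE]
  tx$utr3 <- unname(utr3[tx$transcript_id])

  ## integrity: summed 3UTR region length must equal the sequence length
  u3 <- regions[regions$region_type == "3UTR", , drop = FALSE]
  lens <- tapply(u3$end - u3$start + 1L, u3$transcript_id, sum)
  have <- tx$transcript_id %in% names(lens)
  if (any(!have))
    stop("transcript with 3'UTR sequence but no 3UTR region rows: ",
         paste(utils::head(tx$transcript_id[!have], 3L), collapse = ", "))
  mism <- nchar(tx$utr3) != as.integer(lens[tx$transcript_id])
  if (any(mism))
    stop("3'UTR sequence length disagrees with region table for: ",
         paste(utils::head(tx$transcript_id[mism], 3L), collapse = ", "))

  short <- nchar(tx$utr3) < minUtrLen
  report <- c(report, short_utr = sum(short))
  tx <- tx[!short, , drop = FALSE]
  rownames(tx) <- NULL
  regions <- regions[regions$transcript_id %in% tx$transcript_id, ,
                     drop = FALSE]
  rownames(regions) <- NULL
  attr(snps, "report") <- NULL
  list(transcripts = tx, regions = regions, snps = snps,
       report = report[report > 0 | names(report) %in%
                         c("multi_allelic", "short_utr")])
}

#' Read a GWAS association table
#'
#' @param path TSV with columns `snp_id`, `p` (and optionally `dataset`).
#' @return data.frame; p-values validated to lie in (0, 1].
#' @export
readGwasTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stopifnotCols(df, c("snp_id", "p"), "GWAS table")
  df$p <- as.numeric(df$p)
  if (any(is.na(df$p)) || any(df$p <= 0) || any(df$p > 1))
    stop("GWAS p-values must lie in (0, 1]")
  df
}

#' Read an LD-pair table
#'
#' @param path TSV with columns `snpA`, `snpB`, `dprime`, `r2`.
#' @return data.frame; D' and r-squared validated to lie in \[0, 1\].
#' @export
readLdPairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stopifnotCols(df, c("snpA", "snpB", "dprime", "r2"), "LD table")
  df$dprime <- as.numeric(df$dprime)
  df$r2 <- as.numeric(df$r2)
  if (any(df$dprime < 0 | df$dprime > 1, na.rm = TRUE) ||
      any(df$r2 < 0 | df$r2 > 1, na.rm = TRUE))
    stop("D' and r2 must lie in [0, 1]")
  df
}

#' Read a two-column gene-to-GO-term annotation table
#'
#' @param path TSV with columns `gene`, `term`.
#' @return data.frame with the two columns, deduplicated.
#' @export
readGoAnnotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stopifnotCols(df, c("gene", "term"), "GO annotation table")
  unique(df)
}

#' Read per-dataset gene sets (disease-related genes)
#'
#' @param path TSV with columns `dataset`, `gene`.
#' @return named list of character vectors, one per dataset.
#' @export
readGeneSets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stopifnotCols(df, c("dataset", "gene"), "gene set table")
  lapply(split(df$gene, df$dataset), unique)
}

#' Read a microRNA-gene co-expression correlation table
#'
#' @param path TSV with columns `mirna_id`, `gene`, `r` (Pearson, in
#'   \[-1, 1\]).
#' @return data.frame.
#' @export
readCoexpression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stopifnotCols(df, c("mirna_id", "gene", "r"), "co-expression table")
  df$r <- as.numeric(df$r)
  if (any(abs(df$r) > 1, na.rm = TRUE))
    stop("correlation coefficients must lie in [-1, 1]")
  df
}

#' Read a generic two-column pair table (e.g. microRNA-disease)
#'
#' @param path TSV with a header naming its two columns.
#' @return data.frame with exactly two character columns.
#' @export
readPairList <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) != 2L)
    stop("pair table must have exactly two columns")
  unique(df)
}

#' Read a one-id-per-line SNP list (e.g. PubMed-positive SNPs)
#'
#' @param path text file, one SNP id per line.
#' @return character vector of unique ids.
#' @export
readSnpList <- function(path) {
  x <- readLines(path, warn = FALSE)
  unique(x[nzchar(trimws(x))])
}

## ---- report writer -------------------------------------------------------

## Column schemas for the deterministic report writer. `key` orders rows,
## `num` columns are serialized with fixed precision, `coord` columns are
## converted 0-based half-open <-> 1-based inclusive at the file boundary.
.reportSchemas <- list(
  sites = list(cols = c("transcript_id", "start", "end", "site_type",
                        "site_seq", "mirnas", "conserved"),
               key = c("transcript_id", "start", "site_type", "site_seq"),
               num = character(0), coord = c("start", "end")),
  effects = list(cols = c("snp_id", "transcript_id", "gene_symbol",
                          "site_start", "site_end", "site_type", "effect",
                          "mirnas"),
                 key = c("snp_id", "transcript_id", "site_start",
                         "site_type", "effect"),
                 num = character(0), coord = c("site_start", "site_end")),
  assignments = list(cols = c("snp_id", "dataset", "inherited_p",
                              "n_proxies", "proxies"),
                     key = c("dataset", "snp_id"),
                     num = "inherited_p", coord = character(0)),
  candidates = list(cols = c("snp_id", "dataset", "gene_symbol",
                             "inherited_p", "terms"),
                    key = c("dataset", "snp_id"),
                    num = "inherited_p", coord = character(0)),
  energies = list(cols = c("snp_id", "site_type", "mirnas", "ddG",
                           "abs_ddG", "n_fallback"),
                  key = c("snp_id", "site_type", "mirnas"),
                  num = c("ddG", "abs_ddG"), coord = character(0)),
  density = list(cols = c("region", "maf_class", "snp_count", "total_kb",
                          "density"),
                 key = c("region", "maf_class"),
                 num = c("total_kb", "density"), coord = character(0)),
  enrichment = list(cols = c("term", "k", "K", "n", "N", "p"),
                    key = "term", num = "p", coord = character(0))
)

#' Write a result table deterministically
#'
#' Rows are sorted by the schema's primary key and floats are serialized
#' with fixed precision, so two runs over the same records produce
#' byte-identical files. Site coordinates are converted to 1-based
#' inclusive on the way out.
#'
#' @param records data.frame conforming to one of the declared schemas.
#' @param path output TSV path.
#' @param kind one of `r paste(names(mressnp:::.reportSchemas), collapse=", ")`.
#' @return invisibly, the path.
#' @seealso [readReport()]
#' @export
writeReport <- function(records, path, kind) {
  sch <- .reportSchemas[[kind]]
  if (is.null(sch))
    stop(sprintf("unknown report kind '%s'", kind))
  .stopifnotCols(records, sch$cols, sprintf("'%s' records", kind))
  df <- as.data.frame(records)[, sch$cols, drop = FALSE]
  for (nc in sch$num) {
    if (any(!is.finite(df[[nc]]))) {
      bad <- which(!is.finite(df[[nc]]))[1L]
      stop(sprintf("non-finite value in column '%s' of '%s' record with key %s",
                   nc, kind,
                   paste(unlist(df[bad, sch$key]), collapse = "/")))
    }
  }
  if (nrow(df)) {
    ord <- do.call(order, df[, sch$key, drop = FALSE])
    df <- df[ord, , drop = FALSE]
    for (cc in sch$coord)
      if (cc %in% c("start", "site_start")) df[[cc]] <- df[[cc]] + 1L
    for (nc in sch$num) df[[nc]] <- sprintf("%.12g", df[[nc]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a report written by [writeReport()]
#'
#' @param path TSV path.
#' @param kind schema name used when writing.
#' @return data.frame in internal conventions (0-based half-open
#'   coordinates).
#' @export
readReport <- function(path, kind) {
  sch <- .reportSchemas[[kind]]
  if (is.null(sch))
    stop(sprintf("unknown report kind '%s'", kind))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stopifnotCols(df, sch$cols, sprintf("'%s' report file", kind))
  if (nrow(df))
    for (cc in sch$coord)
      if (cc %in% c("start", "site_start")) df[[cc]] <- df[[cc]] - 1L
  df
}

#' Default pipeline configuration
#'
#' Every threshold used by the pipeline, overridable through a YAML file
#' (see [readPipelineConfig()]).
#'
#' @return named list of parameters: `min_utr_len` (50), `flank` (50),
#'   `p_snp` (0.01), `p_go` (0.05), `maf_common` (0.01),
#'   `min_chromosomes` (100), `dprime_min` (1.0), `gap_open` (10),
#'   `gap_extend` (4), `ld_group_rule` ("component"),
#'   `clamp_fallback_dG37` (1000).
#' @export
defaultConfig <- function() {
  list(min_utr_len = 50L, flank = 50L, p_snp = 0.01, p_go = 0.05,
       maf_common = 0.01, min_chromosomes = 100L, dprime_min = 1.0,
       gap_open = 10, gap_extend = 4, ld_group_rule = "component",
       clamp_fallback_dG37 = 1000)
}

#' Read a YAML pipeline configuration
#'
#' Unset keys fall back to [defaultConfig()]; unknown keys are an error.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return named list of parameters.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, user)
}
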