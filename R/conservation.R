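## Human-mouse conservation filter.
##
## One global alignment per transcript (computed in a single vectorized
## pairwiseAlignment call); a site is conserved only when its whole
## footprint is aligned gap-free to identical mouse bases.

## Per-transcript alignment maps: for each human position (1-based),
## whether it is aligned gap-free to a mouse base and whether that base
## is identical. Transcripts missing from mouseUtrs are absent from the
## result.
.conservationMaps <- function(humanUtrs, mouseUtrs, txs,
                              gapOpen = 10, gapExtend = 4,
                              match = 1, mismatch = -1) {
  txs <- intersect(txs, names(mouseUtrs))
  txs <- txs[nzchar(mouseUtrs[txs]) & !is.na(mouseUtrs[txs])]
  if (length(txs) == 0L) return(list())
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  h <- Biostrings::DNAStringSet(chartr("U", "T", humanUtrs[txs]))
  m <- Biostrings::DNAStringSet(chartr("U", "T", mouseUtrs[txs]))
  aln <- Biostrings::pairwiseAlignment(
    h, m, type = "global", substitutionMatrix = submat,
    gapOpening = gapOpen, gapExtension = gapExtend)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  maps <- vector("list", length(txs))
  names(maps) <- txs
  for (i in seq_along(txs)) {
    p <- strsplit(pa[i], "", fixed = TRUE)[[1L]]
    s <- strsplit(sa[i], "", fixed = TRUE)[[1L]]
    hp <- cumsum(p != "-")          # 1-based human position per column
    aligned <- p != "-" & s != "-"
    identical_ <- aligned & p == s
    n <- nchar(humanUtrs[[txs[i]]])
    ok_ident <- ok_aligned <- rep(FALSE, n)
    ok_ident[hp[identical_]] <- TRUE
    ok_aligned[hp[aligned]] <- TRUE
    maps[[i]] <- list(ident = ok_ident, aligned = ok_aligned)
  }
  maps
}

#' Flag seed sites conserved between human and mouse 3'UTRs
#'
#' Computes a global (end-to-end) pairwise alignment per transcript
#' (match +1, mismatch -1, gap opening -10, gap extension -4 by default)
#' and marks a site conserved only when every base of its footprint is
#' aligned gap-free to an identical mouse base. Positions listed in
#' `exempt` (typically the SNP position for mutant-created sites, which do
#' not exist in the reference sequence) must still be aligned gap-free but
#' are excused from base identity.
#'
#' @param sites site data.frame from [scanSites()] (only `transcript_id`,
#'   `start`, `end` are consulted).
#' @param humanUtrs,mouseUtrs named character vectors of 3'UTR RNA
#'   sequences; transcripts missing from `mouseUtrs` have all their sites
#'   flagged unconserved with a warning.
#' @param gapOpen,gapExtend gap penalties as positive costs (defaults 10
#'   and 4).
#' @param match,mismatch substitution scores (defaults +1 / -1).
#' @param exempt optional data.frame with columns `transcript_id`, `pos`
#'   (0-based UTR offsets excused from base identity).
#' @param maps precomputed alignment maps (internal reuse); computed from
#'   the sequences when NULL.
#' @return `sites` with the `conserved` column filled in.
#' @export
conservationFilter <- function(sites, humanUtrs, mouseUtrs,
                               gapOpen = 10, gapExtend = 4,
                               match = 1, mismatch = -1, exempt = NULL,
                               maps = NULL) {
  if (nrow(sites) == 0L) return(sites)
  humanUtrs <- .normalizeRna(humanUtrs)
  mouseUtrs <- .normalizeRna(mouseUtrs)
  txs <- unique(sites$transcript_id)
  miss <- setdiff(txs, names(humanUtrs))
  if (length(miss))
    stop("no human 3'UTR sequence for: ",
         paste(utils::head(miss, 3L), collapse = ", "))
  if (is.null(maps))
    maps <- .conservationMaps(humanUtrs, mouseUtrs, txs, gapOpen,
                              gapExtend, match, mismatch)
  sites$conserved <- FALSE
  n_missing <- 0L
  for (tx in txs) {
    mp <- maps[[tx]]
    if (is.null(mp)) { n_missing <- n_missing + 1L; next }
    ex <- integer(0)
    if (!is.null(exempt))
      ex <- exempt$pos[exempt$transcript_id == tx] + 1L
    for (i in which(sites$transcript_id == tx)) {
      span <- (sites$start[i] + 1L):sites$end[i]
      need_ident <- setdiff(span, ex)
      sites$conserved[i] <- all(mp$ident[need_ident]) &&
        all(mp$aligned[span])
    }
  }
  if (n_missing)
    warning(sprintf("no mouse ortholog sequence for %d transcript(s); their sites flagged unconserved",
                    n_missing))
  sites
}
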