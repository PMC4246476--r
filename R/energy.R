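## Nearest-neighbor RNA/RNA duplex thermodynamics.
##
## A duplex is summed over adjacent base-pair stacks plus an initiation
## term; free energy at 37 C is dG37 = dH - 310.15 * dS (dH in cal/mol,
## dS in cal/(mol*K)). Watson-Crick stack parameters ship in
## extdata/rna_nn_params.tsv (published 1 M Na+ measurements); any stack
## touching a non-canonical pair (including G:U) falls back to a
## configurable destabilization term and is counted in `n_fallback`.
## Because both allele duplexes share the clamp and initiation terms,
## delta-delta-G for an interior SNP is independent of both.

## stack key for pair1 = (top1, bottom1), pair2 = (top2, bottom2),
## top strand 5'->3'
.stackKey <- function(t1, b1, t2, b2) paste0(t1, b1, ".", t2, b2)

#' Load the nearest-neighbor parameter table
#'
#' Reads the shipped Watson-Crick stack table and expands it to all 16
#' oriented stacks through strand-order symmetry (reading the duplex from
#' the other strand's 5' end leaves its thermodynamics unchanged).
#'
#' @param path TSV with columns `stack`, `dH_cal_mol`, `dS_cal_molK`,
#'   `source`; default the packaged table.
#' @param fallback_dG37 destabilization assigned to a stack involving a
#'   non-canonical pair, in cal/mol at 37 C with dH = 0 (default +1000).
#' @return list with `dH`, `dS` (named vectors over stack keys), `init`,
#'   `term_AU` (2-vectors dH/dS) and `fallback`.
#' @export
loadNnParams <- function(path = NULL, fallback_dG37 = 1000) {
  if (is.null(path))
    path <- system.file("extdata", "rna_nn_params.tsv", package = "mressnp",
                        mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  .stopifnotCols(tab, c("stack", "dH_cal_mol", "dS_cal_molK"),
                 "nearest-neighbor parameter table")
  special <- tab$stack %in% c("init", "term_AU")
  st <- tab[!special, , drop = FALSE]
  dH <- stats::setNames(st$dH_cal_mol, st$stack)
  dS <- stats::setNames(st$dS_cal_molK, st$stack)
  ## strand-order symmetry: (p1, p2) == (rev p2, rev p1)
  sym <- function(key) {
    p1 <- substr(key, 1L, 2L); p2 <- substr(key, 4L, 5L)
    paste0(substr(p2, 2L, 2L), substr(p2, 1L, 1L), ".",
           substr(p1, 2L, 2L), substr(p1, 1L, 1L))
  }
  for (k in names(dH)) {
    k2 <- sym(k)
    if (!k2 %in% names(dH)) {
      dH[k2] <- dH[[k]]
      dS[k2] <- dS[[k]]
    }
  }
  grab <- function(name) {
    r <- tab[tab$stack == name, , drop = FALSE]
    if (nrow(r) != 1L) stop(sprintf("parameter '%s' missing", name))
    c(dH = r$dH_cal_mol, dS = r$dS_cal_molK)
  }
  list(dH = dH, dS = dS, init = grab("init"), term_AU = grab("term_AU"),
       fallback = c(dH = 0, dS = -fallback_dG37 / 310.15))
}

#' Nearest-neighbor energy of one microRNA/target duplex
#'
#' The two segments pair antiparallel position-by-position (microRNA base
#' 1 against the target's 3'-most base). Three complementary clamp pairs
#' (default C:G) are appended to both ends before summation so that
#' terminal mismatches are bracketed by defined stacks.
#'
#' @param mirnaSeg microRNA-side RNA segment, 5' to 3'.
#' @param targetSeg target-side RNA segment, 5' to 3', same length.
#' @param params parameter list from [loadNnParams()].
#' @param clamp clamp bases added on the microRNA strand (default "CCC");
#'   the target strand gets their complements.
#' @return list with `dH` (cal/mol), `dS` (cal/(mol*K)), `dG37` (cal/mol)
#'   and `n_fallback` (stacks priced by the fallback term).
#' @export
duplexEnergy <- function(mirnaSeg, targetSeg, params = loadNnParams(),
                         clamp = "CCC") {
  mirnaSeg <- .normalizeRna(mirnaSeg)
  targetSeg <- .normalizeRna(targetSeg)
  .checkRna(c(mirnaSeg, targetSeg), "duplex segment")
  if (nchar(mirnaSeg) != nchar(targetSeg))
    stop("duplex segments must have equal length")
  if (nchar(mirnaSeg) < 1L) stop("empty duplex")
  cl <- strsplit(.normalizeRna(clamp), "")[[1L]]
  top <- c(cl, strsplit(mirnaSeg, "")[[1L]], cl)
  bot <- c(.compRna(cl), rev(strsplit(targetSeg, "")[[1L]]), .compRna(cl))
  n <- length(top)
  dH <- params$init[["dH"]]
  dS <- params$init[["dS"]]
  n_fallback <- 0L
  wc <- .isWcPair(top, bot)
  for (i in seq_len(n - 1L)) {
    if (wc[i] && wc[i + 1L]) {
      key <- .stackKey(top[i], bot[i], top[i + 1L], bot[i + 1L])
      dH <- dH + params$dH[[key]]
      dS <- dS + params$dS[[key]]
    } else {
      dH <- dH + params$fallback[["dH"]]
      dS <- dS + params$fallback[["dS"]]
      n_fallback <- n_fallback + 1L
    }
  }
  for (i in c(1L, n))  # terminal A:U penalty (clamped duplexes skip this)
    if ((top[i] == "A" && bot[i] == "U") || (top[i] == "U" && bot[i] == "A")) {
      dH <- dH + params$term_AU[["dH"]]
      dS <- dS + params$term_AU[["dS"]]
    }
  list(dH = dH, dS = dS, dG37 = dH - 310.15 * dS, n_fallback = n_fallback)
}

.seedSegment <- function(mirnaSeq, siteType) {
  switch(siteType,
         "7mer(1-7)" = substr(mirnaSeq, 1L, 7L),
         "7mer(2-8)" = substr(mirnaSeq, 2L, 8L),
         "8mer" = ,
         "8mer-1a" = substr(mirnaSeq, 1L, 8L),
         stop(sprintf("unknown site type '%s'", siteType)))
}

#' Allele-specific binding free-energy change for one SNP site
#'
#' Computes the seed-segment duplex energy against the site footprint
#' carrying each allele; delta-delta-G is alternate minus reference. When
#' several microRNAs back the site, the energies are averaged over the
#' members and the result flagged.
#'
#' @param mirnaSeqs named character vector of mature sequences covering
#'   every id in `mirnaIds`.
#' @param mirnaIds character vector of member microRNA ids.
#' @param siteType one of the four site types.
#' @param wildSite,mutSite site footprint RNA sequences (sense strand)
#'   carrying the reference and the alternate allele; must differ at
#'   exactly one position (or be identical, giving 0).
#' @param params parameter list from [loadNnParams()].
#' @param clamp clamp bases (default "CCC").
#' @return list with `ddG`, `abs_ddG` (cal/mol), `n_members`,
#'   `n_fallback` (max over the allele duplexes), `averaged`.
#' @export
snpDelta <- function(mirnaSeqs, mirnaIds, siteType, wildSite, mutSite,
                     params = loadNnParams(), clamp = "CCC") {
  if (nchar(wildSite) != nchar(mutSite))
    stop("allele site sequences must have equal length")
  diff <- which(strsplit(wildSite, "")[[1L]] != strsplit(mutSite, "")[[1L]])
  if (length(diff) > 1L)
    stop("allele site sequences differ at more than one position")
  miss <- setdiff(mirnaIds, names(mirnaSeqs))
  if (length(miss))
    stop("no mature sequence for microRNA(s): ",
         paste(miss, collapse = ", "))
  dd <- nf <- numeric(length(mirnaIds))
  for (i in seq_along(mirnaIds)) {
    seg <- .seedSegment(mirnaSeqs[[mirnaIds[i]]], siteType)
    if (nchar(seg) != nchar(wildSite))
      stop(sprintf("site footprint length %d does not match %s segment",
                   nchar(wildSite), siteType))
    ref <- duplexEnergy(seg, wildSite, params, clamp)
    alt <- duplexEnergy(seg, mutSite, params, clamp)
    dd[i] <- alt$dG37 - ref$dG37
    nf[i] <- max(ref$n_fallback, alt$n_fallback)
  }
  list(ddG = mean(dd), abs_ddG = abs(mean(dd)),
       n_members = length(mirnaIds), n_fallback = as.integer(max(nf)),
       averaged = length(mirnaIds) > 1L)
}

#' Energy table for a set of allelic effects
#'
#' Reconstructs each effect's wild and mutant site footprints from the
#' transcript sequences and SNP alleles and computes delta-delta-G per
#' effect row.
#'
#' @param effects allelic-effect data.frame from [scanAllelicEffects()].
#' @param transcripts,regions,snps reference tables (see
#'   [loadReference()]).
#' @param mirnaSeqs named character vector of mature microRNA sequences.
#' @param params parameter list from [loadNnParams()].
#' @param clamp clamp bases (default "CCC").
#' @return `effects` with added columns `ddG`, `abs_ddG`, `n_fallback`,
#'   `averaged`.
#' @export
energyTable <- function(effects, transcripts, regions, snps, mirnaSeqs,
                        params = loadNnParams(), clamp = "CCC") {
  if (nrow(effects) == 0L) {
    effects$ddG <- numeric(0); effects$abs_ddG <- numeric(0)
    effects$n_fallback <- integer(0); effects$averaged <- logical(0)
    return(effects)
  }
  ## one cached UTR offset per (transcript, SNP) pair
  u3 <- regions[regions$region_type == "3UTR", , drop = FALSE]
  u3split <- split(u3, u3$transcript_id)
  offset_cache <- new.env(parent = emptyenv())
  getOffset <- function(tx, snp_id, pos) {
    key <- paste0(tx, "\r", snp_id)
    if (!is.null(offset_cache[[key]])) return(offset_cache[[key]])
    r <- u3split[[tx]]
    strand <- r$strand[1L]
    r <- r[order(r$start, decreasing = (strand == "-")), , drop = FALSE]
    w <- r$end - r$start + 1L
    before <- cumsum(c(0L, w))[seq_len(nrow(r))]
    hit <- which(pos >= r$start & pos <= r$end)[1L]
    val <- if (is.na(hit)) NA_integer_
           else if (strand == "+") before[hit] + (pos - r$start[hit])
           else before[hit] + (r$end[hit] - pos)
    offset_cache[[key]] <- val
    val
  }
  ddG <- nfb <- numeric(nrow(effects))
  avg <- logical(nrow(effects))
  for (i in seq_len(nrow(effects))) {
    tx <- effects$transcript_id[i]
    ti <- match(tx, transcripts$transcript_id)
    si <- match(effects$snp_id[i], snps$snp_id)
    utr <- transcripts$utr3[ti]
    pos0 <- getOffset(tx, effects$snp_id[i], snps$pos[si])
    ref <- snps$ref_allele[si]; alt <- snps$alt_allele[si]
    if (transcripts$strand[ti] == "-") {
      ref <- .compDna(ref); alt <- .compDna(alt)
    }
    wild <- substr(utr, effects$site_start[i] + 1L, effects$site_end[i])
    off <- pos0 - effects$site_start[i]
    if (off < 0L || off >= nchar(wild))
      stop(sprintf("SNP %s outside site footprint", effects$snp_id[i]))
    mut <- wild
    substr(mut, off + 1L, off + 1L) <- .normalizeRna(alt)
    members <- strsplit(effects$mirnas[i], ",", fixed = TRUE)[[1L]]
    d <- snpDelta(mirnaSeqs, members, effects$site_type[i], wild, mut,
                  params, clamp)
    ddG[i] <- d$ddG; nfb[i] <- d$n_fallback; avg[i] <- d$averaged
  }
  effects$ddG <- ddG
  effects$abs_ddG <- abs(ddG)
  effects$n_fallback <- as.integer(nfb)
  effects$averaged <- avg
  effects
}

#' Per-SNP delta-delta-G summary
#'
#' A SNP can touch several sites; its single score is the mean of the
#' per-effect `abs_ddG` values (and the mean signed `ddG`).
#'
#' @param energies output of [energyTable()].
#' @return data.frame with columns `snp_id`, `transcript_id`, `ddG`,
#'   `abs_ddG`.
#' @export
snpEnergySummary <- function(energies) {
  if (nrow(energies) == 0L)
    return(data.frame(snp_id = character(0), transcript_id = character(0),
                      ddG = numeric(0), abs_ddG = numeric(0),
                      stringsAsFactors = FALSE))
  key <- paste(energies$snp_id, energies$transcript_id, sep = "\r")
  sp <- split(seq_len(nrow(energies)), key)
  idx <- vapply(sp, `[`, integer(1L), 1L)
  out <- data.frame(
    snp_id = energies$snp_id[idx],
    transcript_id = energies$transcript_id[idx],
    ddG = vapply(sp, function(j) mean(energies$ddG[j]), numeric(1L)),
    abs_ddG = vapply(sp, function(j) mean(energies$abs_ddG[j]),
                     numeric(1L)),
    stringsAsFactors = FALSE)
  out <- out[order(out$snp_id, out$transcript_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Haplotype scores: accumulated |delta-delta-G| over linked SNPs
#'
#' Within each transcript's 3'UTR, SNPs are grouped by the LD rule
#' (connected components of the graph whose edges satisfy
#' `measure >= threshold`, or maximal cliques); groups of at least two
#' SNPs are emitted with the sum of their members' absolute
#' delta-delta-G.
#'
#' @param deltas per-SNP data.frame from [snpEnergySummary()].
#' @param ldPairs data.frame with columns `snpA`, `snpB`, `dprime`, `r2`.
#' @param measure `"dprime"` (default) or `"r2"`.
#' @param threshold LD threshold (default 1.0).
#' @param grouping `"component"` (default) or `"clique"`.
#' @return data.frame with columns `transcript_id`, `members`
#'   (comma-joined SNP ids), `n_members`, `score` (cal/mol).
#' @export
haplotypeScores <- function(deltas, ldPairs, measure = c("dprime", "r2"),
                            threshold = 1.0,
                            grouping = c("component", "clique")) {
  measure <- match.arg(measure)
  grouping <- match.arg(grouping)
  empty <- data.frame(transcript_id = character(0), members = character(0),
                      n_members = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(deltas) == 0L || nrow(ldPairs) == 0L) return(empty)
  ld <- ldPairs[ldPairs[[measure]] >= threshold, , drop = FALSE]
  out <- list()
  for (tx in unique(deltas$transcript_id)) {
    d <- deltas[deltas$transcript_id == tx, , drop = FALSE]
    if (nrow(d) < 2L) next
    e <- ld[ld$snpA %in% d$snp_id & ld$snpB %in% d$snp_id, , drop = FALSE]
    if (nrow(e) == 0L) next
    g <- igraph::graph_from_data_frame(e[, c("snpA", "snpB")],
                                       directed = FALSE,
                                       vertices = d$snp_id)
    groups <- if (grouping == "component") {
      comp <- igraph::components(g)
      split(names(comp$membership), comp$membership)
    } else {
      lapply(igraph::max_cliques(g, min = 2L), function(v)
        igraph::V(g)$name[v])
    }
    for (mem in groups) {
      if (length(mem) < 2L) next
      mem <- sort(mem)
      out[[length(out) + 1L]] <- data.frame(
        transcript_id = tx, members = paste(mem, collapse = ","),
        n_members = length(mem),
        score = sum(d$abs_ddG[match(mem, d$snp_id)]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$transcript_id, res$members), , drop = FALSE]
  rownames(res) <- NULL
  res
}
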