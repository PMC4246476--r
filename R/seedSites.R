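## Seed extraction, seed-site scanning and allele-aware create/loss calls.
##
## A seed site is the 3'UTR stretch whose sequence is the reverse
## complement of a microRNA seed. Two seed definitions are used: mature
## positions 1-7 and 2-8. A 7-nt match is upgraded to an 8mer when the
## adjacent UTR base also pairs the microRNA's eighth (kind 1-7) or first
## (kind 2-8) base; a 2-8 match followed 3'-ward by an adenosine that does
## not pair position 1 is an 8mer-1a.

#' Extract seed groups from mature microRNA sequences
#'
#' Builds the two seed sets (positions 1-7 and 2-8 from the 5' end) and
#' groups microRNAs sharing a seed. Sequences shorter than 8 nt cannot
#' provide both seeds and are excluded with a warning.
#'
#' @param mirnas named character vector of mature RNA sequences.
#' @return a [SeedGroups-class] object.
#' @export
#' @examples
#' extractSeeds(c(`hsa-miR-x` = "GAGCUUAUCAGACUGAUGUUGA"))
extractSeeds <- function(mirnas) {
  if (is.null(names(mirnas)) || any(!nzchar(names(mirnas))))
    stop("microRNA sequences must be named")
  mirnas <- .normalizeRna(mirnas)
  .checkRna(mirnas, "microRNA sequence")
  short <- nchar(mirnas) < 8L
  if (any(short)) {
    warning(sprintf("excluding %d microRNA(s) shorter than 8 nt: %s",
                    sum(short),
                    paste(utils::head(names(mirnas)[short], 3L),
                          collapse = ", ")))
    mirnas <- mirnas[!short]
  }
  ids <- names(mirnas)
  members <- rbind(
    data.frame(seed_kind = "1-7", seed = substr(mirnas, 1L, 7L),
               mirna_id = ids, extra_base = substr(mirnas, 8L, 8L),
               stringsAsFactors = FALSE),
    data.frame(seed_kind = "2-8", seed = substr(mirnas, 2L, 8L),
               mirna_id = ids, extra_base = substr(mirnas, 1L, 1L),
               stringsAsFactors = FALSE))
  rownames(members) <- NULL
  methods::new("SeedGroups", members = members)
}

.emptySites <- function() {
  data.frame(transcript_id = character(0), start = integer(0),
             end = integer(0), site_type = character(0),
             site_seq = character(0), mirnas = character(0),
             conserved = logical(0), stringsAsFactors = FALSE)
}

#' Scan 3'UTR sequences for microRNA seed-match sites
#'
#' Finds every occurrence of the reverse complement of each group's seed
#' and types it as `7mer(1-7)`, `7mer(2-8)`, `8mer-1a` or `8mer`. Typing is
#' member-aware: within one seed group, members whose extra base pairs the
#' adjacent UTR base yield an 8mer while the others keep the 7-nt type.
#' Identical 8mer calls arising from both seed kinds are deduplicated.
#'
#' @param utrs named character vector of 3'UTR RNA sequences (sense,
#'   5'-to-3').
#' @param groups a [SeedGroups-class] object.
#' @return data.frame with columns `transcript_id`, `start`, `end`
#'   (0-based half-open offsets in the UTR), `site_type`, `site_seq`,
#'   `mirnas` (comma-joined member ids) and `conserved` (NA until
#'   [conservationFilter()] is applied), sorted by
#'   (transcript, start, type, sequence).
#' @export
scanSites <- function(utrs, groups) {
  stopifnot(methods::is(groups, "SeedGroups"))
  if (length(utrs) == 0L) return(.emptySites())
  if (is.null(names(utrs)) || any(!nzchar(names(utrs))))
    stop("UTR sequences must be named")
  utrs <- .normalizeRna(utrs)
  .checkRna(utrs, "3'UTR sequence")

  members <- seedMembers(groups)
  if (nrow(members) == 0L) return(.emptySites())
  pat_tbl <- unique(members[, c("seed_kind", "seed")])
  pat_tbl$pattern <- .rcRna(pat_tbl$seed)
  upat <- unique(pat_tbl$pattern)

  ## one matchPDict pass over all UTRs joined with N spacers (patterns are
  ## N-free, so no match can span a boundary)
  sep <- strrep("N", 8L)
  dna <- chartr("U", "T", utrs)
  subject <- Biostrings::DNAString(paste(dna, collapse = sep))
  offs <- cumsum(c(0L, nchar(dna) + 8L))[seq_along(dna)]
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(chartr("U", "T", upat)))
  mi <- Biostrings::matchPDict(pd, subject)
  starts <- Biostrings::startIndex(mi)

  hit_list <- lapply(seq_along(upat), function(i) {
    st <- starts[[i]]
    if (is.null(st) || length(st) == 0L) return(NULL)
    tx_idx <- findInterval(st, offs + 1L)
    data.frame(pattern = upat[i], tx_idx = tx_idx,
               s = st - 1L - offs[tx_idx], stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hit_list)
  if (is.null(hits) || nrow(hits) == 0L) return(.emptySites())

  ## expand to (seed kind, seed) entries sharing a pattern, then to members
  hits <- merge(hits, pat_tbl, by = "pattern")
  hits <- merge(hits, members, by = c("seed_kind", "seed"))
  tx_id <- names(utrs)[hits$tx_idx]
  seqlen <- nchar(utrs)[hits$tx_idx]
  utr_of <- utrs[hits$tx_idx]
  s <- hits$s
  want <- .compRna(hits$extra_base)  # UTR base that would pair the extra base

  is17 <- hits$seed_kind == "1-7"
  left <- ifelse(is17 & s > 0L, substr(utr_of, s, s), NA_character_)
  right <- ifelse(!is17 & s + 7L < seqlen,
                  substr(utr_of, s + 8L, s + 8L), NA_character_)

  type <- character(nrow(hits))
  start <- s
  end <- s + 7L
  up17 <- is17 & !is.na(left) & left == want
  type[is17] <- "7mer(1-7)"
  type[up17] <- "8mer"
  start[up17] <- s[up17] - 1L
  up28 <- !is17 & !is.na(right) & right == want
  a28 <- !is17 & !up28 & !is.na(right) & right == "A"
  type[!is17] <- "7mer(2-8)"
  type[up28] <- "8mer"
  type[a28] <- "8mer-1a"
  end[up28 | a28] <- s[up28 | a28] + 8L

  df <- data.frame(transcript_id = tx_id, start = start, end = end,
                   site_type = type, mirna_id = hits$mirna_id,
                   stringsAsFactors = FALSE)
  df <- unique(df)  # dedupe 8mers discovered via both seed kinds
  key <- paste(df$transcript_id, df$start, df$end, df$site_type, sep = "\r")
  agg <- tapply(df$mirna_id, key, function(x)
    paste(sort(unique(x)), collapse = ","))
  first <- !duplicated(key)
  out <- df[first, c("transcript_id", "start", "end", "site_type")]
  out$site_seq <- substr(utrs[match(out$transcript_id, names(utrs))],
                         out$start + 1L, out$end)
  out$mirnas <- unname(agg[key[first]])
  out$conserved <- NA
  out <- out[order(out$transcript_id, out$start, out$site_type,
                   out$site_seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.emptyEffects <- function() {
  data.frame(snp_id = character(0), transcript_id = character(0),
             gene_symbol = character(0), site_start = integer(0),
             site_end = integer(0), site_type = character(0),
             effect = character(0), mirnas = character(0),
             stringsAsFactors = FALSE)
}

## member-level site keys for one scanned window
.memberKeys <- function(sites, po) {
  if (nrow(sites) == 0L) return(sites[0, ])
  keep <- sites$start <= po & po < sites$end
  sites <- sites[keep, , drop = FALSE]
  if (nrow(sites) == 0L) return(sites)
  n <- strsplit(sites$mirnas, ",", fixed = TRUE)
  idx <- rep(seq_len(nrow(sites)), lengths(n))
  out <- sites[idx, c("start", "end", "site_type"), drop = FALSE]
  out$mirna_id <- unlist(n)
  out
}

#' Call create/loss effects of one SNP on seed sites
#'
#' Extracts the window of `flank` bases on both sides of the SNP
#' (truncated at the UTR boundaries), scans it once with the reference
#' allele and once with the alternate allele, and compares the sites whose
#' footprint covers the SNP. A site present only with the reference allele
#' is a `loss`; only with the alternate allele, a `create`. A site whose
#' type changes between alleles at the same locus yields one loss (the
#' reference type) and one create (the alternate type).
#'
#' @param utr 3'UTR RNA sequence (sense orientation).
#' @param pos0 0-based offset of the SNP in the UTR.
#' @param ref,alt reference and alternate alleles as sense-strand RNA
#'   bases.
#' @param groups a [SeedGroups-class] object.
#' @param flank window half-width in bases (default 50).
#' @param snpId,transcriptId,gene identifiers copied into the output.
#' @return data.frame of allelic effects (see [scanAllelicEffects()] for
#'   the columns); zero rows when the SNP touches no site.
#' @export
callAllelicEffects <- function(utr, pos0, ref, alt, groups, flank = 50L,
                               snpId = "snp", transcriptId = "tx",
                               gene = NA_character_) {
  utr <- .normalizeRna(utr)
  ref <- .normalizeRna(ref); alt <- .normalizeRna(alt)
  n <- nchar(utr)
  if (pos0 < 0L || pos0 >= n)
    stop(sprintf("SNP %s lies outside the 3'UTR", snpId))
  have <- substr(utr, pos0 + 1L, pos0 + 1L)
  if (have != ref)
    stop(sprintf("reference allele mismatch for %s: sequence has %s, table says %s",
                 snpId, have, ref))
  wl <- max(0L, pos0 - flank)
  wr <- min(n, pos0 + flank + 1L)
  wild <- substr(utr, wl + 1L, wr)
  po <- pos0 - wl
  mut <- wild
  substr(mut, po + 1L, po + 1L) <- alt

  sw <- .memberKeys(scanSites(c(w = wild), groups), po)
  sm <- .memberKeys(scanSites(c(w = mut), groups), po)
  kw <- paste(sw$start, sw$end, sw$site_type, sw$mirna_id, sep = "\r")
  km <- paste(sm$start, sm$end, sm$site_type, sm$mirna_id, sep = "\r")
  loss <- sw[!(kw %in% km), , drop = FALSE]
  create <- sm[!(km %in% kw), , drop = FALSE]
  if (nrow(loss)) loss$effect <- "loss"
  if (nrow(create)) create$effect <- "create"
  eff <- rbind(loss, create)
  if (nrow(eff) == 0L) return(.emptyEffects())

  key <- paste(eff$start, eff$end, eff$site_type, eff$effect, sep = "\r")
  agg <- tapply(eff$mirna_id, key, function(x)
    paste(sort(unique(x)), collapse = ","))
  first <- !duplicated(key)
  out <- data.frame(snp_id = snpId, transcript_id = transcriptId,
                    gene_symbol = gene,
                    site_start = eff$start[first] + wl,
                    site_end = eff$end[first] + wl,
                    site_type = eff$site_type[first],
                    effect = eff$effect[first],
                    mirnas = unname(agg[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$site_start, out$site_type, out$effect), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a genomic SNP position into 3'UTR offset coordinates
#'
#' @param regions region-table rows (all transcripts); only `3UTR` rows of
#'   `transcriptId` are used.
#' @param transcriptId transcript accession.
#' @param pos 1-based genomic position.
#' @return 0-based offset within the spliced sense-orientation 3'UTR, or
#'   NA if the position is not inside it.
#' @export
mapSnpToUtr <- function(regions, transcriptId, pos) {
  r <- regions[regions$transcript_id == transcriptId &
                 regions$region_type == "3UTR", , drop = FALSE]
  if (nrow(r) == 0L) return(NA_integer_)
  strand <- r$strand[1L]
  r <- r[order(r$start, decreasing = (strand == "-")), , drop = FALSE]
  w <- r$end - r$start + 1L
  before <- cumsum(c(0L, w))[seq_len(nrow(r))]
  hit <- which(pos >= r$start & pos <= r$end)
  if (length(hit) == 0L) return(NA_integer_)
  hit <- hit[1L]
  if (strand == "+") before[hit] + (pos - r$start[hit])
  else before[hit] + (r$end[hit] - pos)
}

#' Call create/loss effects for a whole SNP table
#'
#' Maps each SNP into any transcript whose 3'UTR contains it (a SNP in two
#' genes' UTRs counts for both), orients forward-strand alleles onto the
#' sense strand (complementing for minus-strand transcripts), builds the
#' wild/mutant windows for every mapped SNP, and scans all windows in two
#' batched passes.
#'
#' @param transcripts data.frame from [loadReference()].
#' @param regions region-table data.frame.
#' @param snps SNP data.frame.
#' @param groups a [SeedGroups-class] object.
#' @param flank window half-width (default 50).
#' @return data.frame with columns `snp_id`, `transcript_id`,
#'   `gene_symbol`, `site_start`, `site_end` (0-based half-open UTR
#'   offsets), `site_type`, `effect` (create/loss), `mirnas`.
#' @export
scanAllelicEffects <- function(transcripts, regions, snps, groups,
                               flank = 50L) {
  if (nrow(snps) == 0L || nrow(transcripts) == 0L) return(.emptyEffects())
  u3 <- regions[regions$region_type == "3UTR" &
                  regions$transcript_id %in% transcripts$transcript_id, ,
                drop = FALSE]
  gr <- GenomicRanges::GRanges(u3$chrom,
                               IRanges::IRanges(u3$start, u3$end))
  sp <- GenomicRanges::GRanges(snps$chrom,
                               IRanges::IRanges(snps$pos, snps$pos))
  ov <- GenomicRanges::findOverlaps(sp, gr)
  if (length(ov) == 0L) return(.emptyEffects())

  ## cumulative sense-orientation offset of each 3'UTR block
  u3 <- u3[order(u3$transcript_id, u3$start), , drop = FALSE]
  ## (re-derive the overlap on the reordered table)
  gr <- GenomicRanges::GRanges(u3$chrom, IRanges::IRanges(u3$start, u3$end))
  ov <- GenomicRanges::findOverlaps(sp, gr)
  w <- u3$end - u3$start + 1L
  cumplus <- stats::ave(w, u3$transcript_id,
                        FUN = function(x) cumsum(x) - x)
  cumminus <- stats::ave(w, u3$transcript_id,
                         FUN = function(x) rev(cumsum(rev(x)) - rev(x)))
  ri <- S4Vectors::subjectHits(ov)
  si <- S4Vectors::queryHits(ov)
  minus_blk <- u3$strand[ri] == "-"
  pos0 <- ifelse(minus_blk,
                 cumminus[ri] + u3$end[ri] - snps$pos[si],
                 cumplus[ri] + snps$pos[si] - u3$start[ri])
  pairs <- data.frame(snp_i = si, transcript_id = u3$transcript_id[ri],
                      pos0 = as.integer(pos0), stringsAsFactors = FALSE)
  pairs <- unique(pairs)

  ti <- match(pairs$transcript_id, transcripts$transcript_id)
  utr <- transcripts$utr3[ti]
  strand <- transcripts$strand[ti]
  n <- nchar(utr)
  pos0 <- pairs$pos0
  if (nrow(pairs) == 0L) return(.emptyEffects())

  ref <- snps$ref_allele[pairs$snp_i]
  alt <- snps$alt_allele[pairs$snp_i]
  minus <- strand == "-"
  ref[minus] <- .compDna(ref[minus])
  alt[minus] <- .compDna(alt[minus])
  ref <- .normalizeRna(ref); alt <- .normalizeRna(alt)

  have <- substr(utr, pos0 + 1L, pos0 + 1L)
  bad <- have != ref
  if (any(bad))
    stop("reference allele mismatch for SNP(s): ",
         paste(utils::head(snps$snp_id[pairs$snp_i][bad], 5L),
               collapse = ", "))

  wl <- pmax(0L, pos0 - flank)
  wr <- pmin(n, pos0 + flank + 1L)
  wild <- substr(utr, wl + 1L, wr)
  po <- pos0 - wl
  mut <- wild
  substr(mut, po + 1L, po + 1L) <- alt
  wname <- sprintf("w%06d", seq_along(wild))
  names(wild) <- wname; names(mut) <- wname

  sw <- scanSites(wild, groups)
  sm <- scanSites(mut, groups)
  per <- function(sites, effect) {
    if (nrow(sites) == 0L) return(NULL)
    wi <- match(sites$transcript_id, wname)
    keep <- sites$start <= po[wi] & po[wi] < sites$end
    sites <- sites[keep, , drop = FALSE]
    if (nrow(sites) == 0L) return(NULL)
    sites$wi <- wi[keep]
    sites$effect <- effect
    sites
  }
  a <- per(sw, "loss")
  b <- per(sm, "create")
  explode <- function(x) {
    if (is.null(x)) return(NULL)
    m <- strsplit(x$mirnas, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(x)), lengths(m))
    out <- x[idx, c("wi", "start", "end", "site_type", "effect")]
    out$mirna_id <- unlist(m)
    out
  }
  a <- explode(a); b <- explode(b)
  kk <- function(x) paste(x$wi, x$start, x$end, x$site_type, x$mirna_id,
                          sep = "\r")
  if (!is.null(a) && !is.null(b)) {
    ka <- kk(a); kb <- kk(b)
    a <- a[!(ka %in% kb), , drop = FALSE]
    b <- b[!(kb %in% ka), , drop = FALSE]
  }
  eff <- rbind(a, b)
  if (is.null(eff) || nrow(eff) == 0L) return(.emptyEffects())

  key <- paste(eff$wi, eff$start, eff$end, eff$site_type, eff$effect,
               sep = "\r")
  agg <- tapply(eff$mirna_id, key, function(x)
    paste(sort(unique(x)), collapse = ","))
  first <- !duplicated(key)
  wi <- eff$wi[first]
  gi <- match(pairs$transcript_id[wi], transcripts$transcript_id)
  out <- data.frame(snp_id = snps$snp_id[pairs$snp_i[wi]],
                    transcript_id = pairs$transcript_id[wi],
                    gene_symbol = transcripts$gene_symbol[gi],
                    site_start = eff$start[first] + wl[wi],
                    site_end = eff$end[first] + wl[wi],
                    site_type = eff$site_type[first],
                    effect = eff$effect[first],
                    mirnas = unname(agg[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$snp_id, out$transcript_id, out$site_start,
                   out$site_type, out$effect), , drop = FALSE]
  rownames(out) <- NULL
  out
}
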