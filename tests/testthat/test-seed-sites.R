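test_that("extractSeeds takes bases 1-7 and 2-8 and groups shared seeds", {
  g <- extractSeeds(c(m1 = "GAGCUUAUCAGACUGAUGUUGA",
                      m2 = "AAGCUUAUCAGACUGAUGUUGA"))
  m <- seedMembers(g)
  expect_equal(m$seed[m$seed_kind == "1-7" & m$mirna_id == "m1"], "GAGCUUA")
  expect_equal(m$seed[m$seed_kind == "2-8" & m$mirna_id == "m1"], "AGCUUAU")
  ## both microRNAs share the 2-8 seed AGCUUAU -> one group, two members
  expect_equal(sort(m$mirna_id[m$seed_kind == "2-8" & m$seed == "AGCUUAU"]),
               c("m1", "m2"))
  ## every microRNA in exactly one group per kind
  expect_equal(as.vector(table(m$seed_kind)), c(2L, 2L))
})

test_that("extractSeeds excludes sub-8nt sequences with a warning", {
  expect_warning(g <- extractSeeds(c(ok = "GAGCUUAUC", short = "GAGCUUA")),
                 "shorter than 8")
  expect_equal(unique(seedMembers(g)$mirna_id), "ok")
})

test_that("scanSites types the four site classes like the oracle", {
  mir <- c(m1 = "GAGCUUAUCAGACUGAUGUUGA")
  g <- extractSeeds(mir)
  ## 2-8 match followed by A, position-1 complement absent -> 8mer-1a
  s1 <- scanSites(c(t1 = "AAAUAAGCUAAA"), g)
  o1 <- oracleScan(c(t1 = "AAAUAAGCUAAA"), mir)
  expect_identical(explodeSites(s1), o1)
  expect_equal(s1$site_type, "8mer-1a")
  expect_equal(s1$site_seq, "AUAAGCUA")
  expect_equal(c(s1$start, s1$end), c(2L, 10L))
  ## position-1 complement present -> full 8mer (deduplicated across kinds)
  s2 <- scanSites(c(t1 = "AAAUAAGCUCAA"), g)
  o2 <- oracleScan(c(t1 = "AAAUAAGCUCAA"), mir)
  expect_identical(explodeSites(s2), o2)
  expect_equal(s2$site_type, "8mer")
  expect_equal(s2$site_seq, "AUAAGCUC")
  ## G/C-containing seed never matches poly-A
  expect_equal(nrow(scanSites(c(t1 = strrep("A", 30L)), g)), 0L)
})

test_that("a U at microRNA position 1 turns an A-followed 2-8 match into an 8mer", {
  mir <- c(mU = "UAGCUUAUCAGACUGAUGUUGA")   # position 1 is U, pairs the A
  g <- extractSeeds(mir)
  s <- scanSites(c(t1 = "AAAUAAGCUAAA"), g)
  expect_identical(explodeSites(s), oracleScan(c(t1 = "AAAUAAGCUAAA"), mir))
  expect_true("8mer" %in% s$site_type)
  expect_false("8mer-1a" %in% s$site_type)
})

test_that("scanSites equals exhaustive enumeration on random sequences", {
  set.seed(42)
  mirnas <- setNames(vapply(1:10, function(i) randomRna(22L),
                            character(1L)),
                     paste0("m", 1:10))
  utrs <- setNames(vapply(1:30, function(i) randomRna(300L), character(1L)),
                   paste0("t", 1:30))
  g <- extractSeeds(mirnas)
  expect_identical(explodeSites(scanSites(utrs, g)),
                   oracleScan(utrs, mirnas))
})

test_that("callAllelicEffects calls loss and create by window comparison", {
  mir <- c(m1 = "GAGCUUAUCAGACUGAUGUUGA")
  g <- extractSeeds(mir)
  ## SNP inside a 7mer(2-8) footprint: alternate allele destroys it
  ## (G flanks: the base after the site neither pairs position 1 nor is A)
  utr <- paste0(strrep("G", 20L), "AUAAGCU", strrep("G", 20L))
  pos <- 24L                         # the G of AUAAGCU (0-based)
  expect_equal(substr(utr, pos + 1L, pos + 1L), "G")
  eff <- callAllelicEffects(utr, pos, "G", "C", g, snpId = "rs1")
  expect_equal(nrow(eff), 1L)
  expect_equal(eff$effect, "loss")
  expect_equal(eff$site_type, "7mer(2-8)")
  expect_equal(c(eff$site_start, eff$site_end), c(20L, 27L))
  ## oracle agreement on both windows
  wild <- oracleScan(c(w = utr), mir)
  mut_seq <- utr; substr(mut_seq, pos + 1L, pos + 1L) <- "C"
  expect_true(nrow(wild) == 1L &&
                nrow(oracleScan(c(w = mut_seq), mir)) == 0L)

  ## SNP far from any site: no effects
  eff2 <- callAllelicEffects(utr, 3L, "G", "A", g)
  expect_equal(nrow(eff2), 0L)
})

test_that("type transitions report the persisting shorter site in neither class", {
  mir <- c(m1 = "GAGCUUAUCAGACUGAUGUUGA")
  g <- extractSeeds(mir)
  ## wild ...AUAAGCUU..., SNP at the trailing U -> A creates an 8mer-1a
  ## while the 7mer(2-8) persists in both alleles (it does not cover the
  ## SNP) and must appear in neither class
  utr <- paste0(strrep("C", 20L), "AUAAGCUU", strrep("C", 20L))
  pos <- 27L
  expect_equal(substr(utr, pos + 1L, pos + 1L), "U")
  eff <- callAllelicEffects(utr, pos, "U", "A", g)
  expect_equal(eff$effect, "create")
  expect_equal(eff$site_type, "8mer-1a")
  expect_false(any(eff$effect == "loss"))
})

test_that("swapping ref and alt swaps create and loss exactly", {
  set.seed(7)
  mirnas <- setNames(vapply(1:5, function(i) randomRna(22L), character(1L)),
                     paste0("m", 1:5))
  g <- extractSeeds(mirnas)
  checked <- 0L
  for (rep in 1:40) {
    ## plant a seed-match site and put the SNP inside its footprint
    mid <- sample(names(mirnas), 1L)
    k0 <- sample(1:2, 1L)
    pat <- oracleRc(substr(mirnas[[mid]], k0, k0 + 6L))
    utr <- paste0(randomRna(30L), pat, randomRna(30L))
    pos <- 30L + sample(0:6, 1L)
    ref <- substr(utr, pos + 1L, pos + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "U"), ref), 1L)
    a <- callAllelicEffects(utr, pos, ref, alt, g)
    utr2 <- utr; substr(utr2, pos + 1L, pos + 1L) <- alt
    b <- callAllelicEffects(utr2, pos, alt, ref, g)
    key <- function(x, eff) {
      y <- x[x$effect == eff, c("site_start", "site_end", "site_type",
                                "mirnas")]
      y <- y[do.call(order, y), , drop = FALSE]; rownames(y) <- NULL; y
    }
    expect_identical(key(a, "loss"), key(b, "create"))
    expect_identical(key(a, "create"), key(b, "loss"))
    checked <- checked + nrow(a)
  }
  expect_gt(checked, 0L)   # the windows really contained sites
})

test_that("callAllelicEffects validates position and reference allele", {
  g <- extractSeeds(c(m1 = "GAGCUUAUCAGACUGAUGUUGA"))
  utr <- randomRna(60L)
  expect_error(callAllelicEffects(utr, 60L, "A", "G", g), "outside")
  ref <- substr(utr, 11L, 11L)
  wrong <- setdiff(c("A", "C", "G", "U"), ref)[1L]
  expect_error(callAllelicEffects(utr, 10L, wrong, "A", g, snpId = "rsX"),
               "rsX")
})

test_that("scanAllelicEffects matches per-SNP calls and minus-strand alleles", {
  set.seed(11)
  mirnas <- setNames(vapply(1:6, function(i) randomRna(22L), character(1L)),
                     paste0("m", 1:6))
  g <- extractSeeds(mirnas)
  ## two transcripts, one on each strand, single-block 3'UTRs
  utr_p <- randomRna(200L); utr_m <- randomRna(200L)
  transcripts <- data.frame(
    transcript_id = c("NM_P", "NM_M"), gene_symbol = c("GP", "GM"),
    chrom = c("chr1", "chr2"), strand = c("+", "-"),
    utr3 = c(utr_p, utr_m), stringsAsFactors = FALSE)
  regions <- data.frame(
    transcript_id = c("NM_P", "NM_M"), gene_symbol = c("GP", "GM"),
    chrom = c("chr1", "chr2"), strand = c("+", "-"),
    region_type = "3UTR", start = c(1001L, 2001L),
    end = c(1200L, 2200L), stringsAsFactors = FALSE)
  ## SNPs at fixed genomic positions; forward-strand alleles
  mkSnp <- function(id, chrom, pos, utr, off, minus) {
    sense_ref <- substr(utr, off + 1L, off + 1L)
    fwd_ref <- chartr("U", "T", sense_ref)
    if (minus) fwd_ref <- chartr("ACGT", "TGCA", fwd_ref)
    alt <- setdiff(c("A", "C", "G", "T"), fwd_ref)[2L]
    data.frame(snp_id = id, chrom = chrom, pos = pos, ref_allele = fwd_ref,
               alt_allele = alt, maf = 0.2, n_chromosomes = 1000L,
               stringsAsFactors = FALSE)
  }
  snps <- rbind(
    mkSnp("rsP", "chr1", 1051L, utr_p, 50L, FALSE),
    mkSnp("rsM", "chr2", 2150L, utr_m, 50L, TRUE))  # off = end - pos = 50
  bulk <- scanAllelicEffects(transcripts, regions, snps, g)

  one <- function(utr, off, snp, minus, id, tx, gene) {
    ref <- snp$ref_allele; alt <- snp$alt_allele
    if (minus) { ref <- chartr("ACGT", "TGCA", ref)
                 alt <- chartr("ACGT", "TGCA", alt) }
    callAllelicEffects(utr, off, chartr("T", "U", ref),
                       chartr("T", "U", alt), g, snpId = id,
                       transcriptId = tx, gene = gene)
  }
  manual <- rbind(one(utr_p, 50L, snps[1L, ], FALSE, "rsP", "NM_P", "GP"),
                  one(utr_m, 50L, snps[2L, ], TRUE, "rsM", "NM_M", "GM"))
  manual <- manual[order(manual$snp_id, manual$transcript_id,
                         manual$site_start, manual$site_type,
                         manual$effect), , drop = FALSE]
  rownames(manual) <- NULL
  expect_identical(bulk, manual)
})

test_that("site ordering is deterministic across runs", {
  set.seed(3)
  mirnas <- setNames(vapply(1:8, function(i) randomRna(22L), character(1L)),
                     paste0("m", 1:8))
  utrs <- setNames(vapply(1:10, function(i) randomRna(400L), character(1L)),
                   paste0("t", 1:10))
  g <- extractSeeds(mirnas)
  a <- scanSites(utrs, g)
  b <- scanSites(utrs[sample(names(utrs))], g)
  expect_identical(a, b)   # output order independent of input order
})
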