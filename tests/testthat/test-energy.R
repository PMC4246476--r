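## independent stack summation over the shipped parameter table,
## trying the written key and its strand-order mirror
oracleDuplex <- function(mirnaSeg, targetSeg, clamp = "CCC") {
  tab <- utils::read.delim(system.file("extdata", "rna_nn_params.tsv",
                                       package = "mressnp"))
  lookup <- function(key) {
    i <- match(key, tab$stack)
    if (!is.na(i)) return(c(tab$dH_cal_mol[i], tab$dS_cal_molK[i]))
    p1 <- substr(key, 1L, 2L); p2 <- substr(key, 4L, 5L)
    mirror <- paste0(substr(p2, 2L, 2L), substr(p2, 1L, 1L), ".",
                     substr(p1, 2L, 2L), substr(p1, 1L, 1L))
    i <- match(mirror, tab$stack)
    if (is.na(i)) stop("no WC entry for ", key)
    c(tab$dH_cal_mol[i], tab$dS_cal_molK[i])
  }
  cl <- strsplit(clamp, "")[[1L]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  top <- c(cl, strsplit(mirnaSeg, "")[[1L]], cl)
  bot <- c(comp[cl], rev(strsplit(targetSeg, "")[[1L]]), comp[cl])
  ini <- tab[tab$stack == "init", ]
  dH <- ini$dH_cal_mol; dS <- ini$dS_cal_molK
  for (i in seq_len(length(top) - 1L)) {
    v <- lookup(paste0(top[i], bot[i], ".", top[i + 1L], bot[i + 1L]))
    dH <- dH + v[1L]; dS <- dS + v[2L]
  }
  c(dH = dH, dS = dS, dG37 = dH - 310.15 * dS)
}

test_that("a fully complementary duplex equals the hand-summed stack total", {
  ## seed positions 1-7 of GAGCUUAU... against its reverse complement
  mir <- "GAGCUUA"; tgt <- "UAAGCUC"
  d <- duplexEnergy(mir, tgt)
  o <- oracleDuplex(mir, tgt)
  expect_equal(d$dH, unname(o["dH"]))
  expect_equal(d$dS, unname(o["dS"]))
  expect_equal(d$dG37, unname(o["dG37"]))
  expect_equal(d$n_fallback, 0L)
  ## determinism
  expect_identical(d, duplexEnergy(mir, tgt))
})

test_that("dG37 identity and strand-order symmetry hold for random duplexes", {
  set.seed(71)
  for (i in 1:20) {
    a <- randomRna(sample(7:8, 1L))
    b <- randomRna(nchar(a))
    d <- duplexEnergy(a, b)
    expect_equal(d$dG37, d$dH - 310.15 * d$dS)
    ## reading the duplex from the other strand's 5' end (which puts the
    ## clamp bases on that strand) changes nothing
    d2 <- duplexEnergy(b, a, clamp = "GGG")
    expect_equal(d$dG37, d2$dG37)
    expect_equal(d$n_fallback, d2$n_fallback)
  }
})

test_that("a single central mismatch destabilizes the duplex", {
  mir <- "GAGCUUA"
  tgt <- "UAAGCUC"                      # perfect complement
  bad <- tgt; substr(bad, 4L, 4L) <- "A"   # G:... mismatch mid-site
  expect_gt(duplexEnergy(mir, bad)$dG37, duplexEnergy(mir, tgt)$dG37)
  expect_equal(duplexEnergy(mir, bad)$n_fallback, 2L)  # two flanking stacks
})

test_that("duplexEnergy validates its inputs", {
  expect_error(duplexEnergy("GAGCUUA", "UAAGCU"), "equal length")
  expect_error(duplexEnergy("GAGCTTA", "UAAGCUC"), NA)  # T normalized to U
  expect_error(duplexEnergy("GAGCXUA", "UAAGCUC"), "non-RNA")
})

test_that("snpDelta is zero for identical alleles and antisymmetric", {
  mirs <- c(m1 = "GAGCUUAUCAGACUGAUGUUGA")
  wild <- "UAAGCUC"; mut <- wild; substr(mut, 4L, 4L) <- "C"
  z <- snpDelta(mirs, "m1", "7mer(1-7)", wild, wild)
  expect_equal(z$ddG, 0)
  a <- snpDelta(mirs, "m1", "7mer(1-7)", wild, mut)
  b <- snpDelta(mirs, "m1", "7mer(1-7)", mut, wild)
  expect_equal(a$ddG, -b$ddG)
  expect_equal(a$abs_ddG, b$abs_ddG)
  ## loss of a perfect match raises the free energy: ddG > 0
  expect_gt(a$ddG, 0)
})

test_that("ddG of an interior SNP ignores clamp and initiation choices", {
  mirs <- c(m1 = "GAGCUUAUCAGACUGAUGUUGA")
  wild <- "UAAGCUC"; mut <- wild; substr(mut, 4L, 4L) <- "A"
  p <- loadNnParams()
  a <- snpDelta(mirs, "m1", "7mer(1-7)", wild, mut, params = p,
                clamp = "CCC")
  b <- snpDelta(mirs, "m1", "7mer(1-7)", wild, mut, params = p,
                clamp = "GAU")
  expect_equal(a$ddG, b$ddG)
  p2 <- p; p2$init <- c(dH = 12345, dS = -67)
  c_ <- snpDelta(mirs, "m1", "7mer(1-7)", wild, mut, params = p2)
  expect_equal(a$ddG, c_$ddG)
})

test_that("multi-member seed groups average per-member energies", {
  ## two members share seed 1-7 but differ at base 8; the 8mer segment
  ## differs, so the energies differ and are averaged with a flag
  mirs <- c(m1 = "GAGCUUAUCAGACUGAUGUUGA",
            m2 = "GAGCUUACCAGACUGAUGUUGA")
  ## the SNP sits at the footprint base pairing microRNA position 8,
  ## where the two members differ (U vs C)
  wild <- "AUAAGCUC"; mut <- wild; substr(mut, 1L, 1L) <- "G"
  d <- snpDelta(mirs, c("m1", "m2"), "8mer", wild, mut)
  d1 <- snpDelta(mirs, "m1", "8mer", wild, mut)
  d2 <- snpDelta(mirs, "m2", "8mer", wild, mut)
  expect_true(d$averaged)
  expect_false(isTRUE(all.equal(d1$ddG, d2$ddG)))
  expect_equal(d$ddG, mean(c(d1$ddG, d2$ddG)))
})

test_that("parameter loading expands strand-order symmetric stacks", {
  p <- loadNnParams()
  expect_equal(p$dH[["GC.GC"]], p$dH[["CG.CG"]])   # 5'GG3'/3'CC5' pair
  expect_equal(p$dH[["CG.UA"]], p$dH[["AU.GC"]])   # 5'CU3'/3'GA5' pair
  ## fallback honors the configured dG37 at 37 C
  p2 <- loadNnParams(fallback_dG37 = 500)
  expect_equal(p2$fallback[["dH"]] - 310.15 * p2$fallback[["dS"]], 500)
})

test_that("haplotype scores sum members under the chosen grouping rule", {
  deltas <- data.frame(snp_id = c("A", "B", "C", "D"),
                       transcript_id = "tx",
                       ddG = c(3000, -4000, 2000, 1000),
                       abs_ddG = c(3000, 4000, 2000, 1000),
                       stringsAsFactors = FALSE)
  ld <- data.frame(snpA = c("A", "B"), snpB = c("B", "C"),
                   dprime = 1, r2 = 0.9, stringsAsFactors = FALSE)
  comp <- haplotypeScores(deltas, ld)
  expect_equal(nrow(comp), 1L)               # D unlinked: no group
  expect_equal(comp$members, "A,B,C")        # chain joins one component
  expect_equal(comp$score, 9000)
  cli <- haplotypeScores(deltas, ld, grouping = "clique")
  expect_equal(sort(cli$members), c("A,B", "B,C"))
  expect_equal(cli$score[cli$members == "A,B"], 7000)
  ## the r2 rule at 0.95 rejects these edges entirely
  expect_equal(nrow(haplotypeScores(deltas, ld, measure = "r2",
                                    threshold = 0.95)), 0L)
})

test_that("energyTable reconstructs footprints and feeds the summary", {
  set.seed(73)
  b <- simulateBundle(simConfig(seed = 73, n_genes = 40L, n_mirnas = 15L,
                                n_snps = 800L, frac_causal = 0))
  g <- extractSeeds(b$mirnas)
  eff <- scanAllelicEffects(b$transcripts, b$regions, b$snps, g)
  expect_gt(nrow(eff), 0L)
  en <- energyTable(eff, b$transcripts, b$regions, b$snps, b$mirnas)
  expect_equal(en$abs_ddG, abs(en$ddG))
  ## losses of fully paired sites are destabilizing
  loss <- en$effect == "loss" & en$n_fallback > 0L & !en$averaged &
    en$site_type %in% c("7mer(1-7)", "7mer(2-8)", "8mer")
  expect_true(all(en$ddG[loss] > 0))
  s <- snpEnergySummary(en)
  expect_true(all(s$abs_ddG >= 0))
  expect_equal(anyDuplicated(paste(s$snp_id, s$transcript_id)), 0L)
})
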