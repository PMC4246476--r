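test_that("MAF classification follows the common/rare/unknown rules", {
  expect_equal(classifyMaf(c(0.05, 0.005, 0.3, NA, 0.01),
                           c(2000L, 120L, 80L, 500L, 100L)),
               c("common", "rare", "unknown", "unknown", "common"))
})

test_that("region density divides merged lengths and counts containment", {
  ## 5 SNPs over 2,500 merged 3'UTR bases -> 2.0 per kb; a SNP inside a
  ## seed-site interval counts in both MRESS and 3UTR; two identical
  ## MRESS intervals merge so their length counts once
  regions <- data.frame(
    transcript_id = c("t1", "t2"), gene_symbol = c("g1", "g2"),
    chrom = "chr1", strand = "+", region_type = "3UTR",
    start = c(1001L, 4001L), end = c(2000L, 5500L),
    stringsAsFactors = FALSE)
  mress <- data.frame(chrom = "chr1", start = c(1101L, 1101L),
                      end = c(1200L, 1200L), stringsAsFactors = FALSE)
  snps <- data.frame(
    snp_id = paste0("rs", 1:5), chrom = "chr1",
    pos = c(1050L, 1150L, 1500L, 4200L, 5400L),
    ref_allele = "A", alt_allele = "G", maf = 0.2,
    n_chromosomes = 1000L, stringsAsFactors = FALSE)
  d <- regionDensity(snps, regions, mress)
  u3c <- d[d$region == "3UTR" & d$maf_class == "common", ]
  expect_equal(u3c$snp_count, 5L)
  expect_equal(u3c$total_kb, 2.5)
  expect_equal(u3c$density, 2.0)
  mr <- d[d$region == "MRESS" & d$maf_class == "common", ]
  expect_equal(mr$snp_count, 1L)         # rs2 in both MRESS and 3UTR
  expect_equal(mr$total_kb, 0.1)         # duplicates merged
  ## empty region class is flagged, not an error
  expect_true(all(d$flagged[d$region == "5UTR"]))
  expect_true(all(is.na(d$density[d$region == "5UTR"])))
})

test_that("density identity and containment hold on simulated data", {
  b <- simulateBundle(simConfig(seed = 31, n_genes = 60L, n_mirnas = 20L,
                                n_snps = 1500L, frac_causal = 0))
  d <- regionDensity(b$snps, b$regions,
                     sitesToGenomic(b$truth$sites, b$regions))
  ok <- !d$flagged
  expect_equal(d$density[ok], d$snp_count[ok] / d$total_kb[ok])
  for (mc in c("common", "rare", "unknown")) {
    expect_lte(d$snp_count[d$region == "MRESS" & d$maf_class == mc],
               d$snp_count[d$region == "3UTR" & d$maf_class == mc])
  }
  expect_lte(d$total_kb[d$region == "MRESS"][1L],
             d$total_kb[d$region == "3UTR"][1L])
  ## the three MAF classes partition each region's mapped SNPs
  cls <- classifyMaf(b$snps$maf, b$snps$n_chromosomes)
  expect_equal(sum(d$snp_count[d$region == "3UTR"]),
               sum(d$snp_count[d$region == "3UTR" &
                                 d$maf_class %in% unique(cls)]))
})

test_that("sitesToGenomic round-trips through mapSnpToUtr on both strands", {
  set.seed(12)
  regions <- data.frame(
    transcript_id = c("P", "P", "M", "M"),
    gene_symbol = c("gp", "gp", "gm", "gm"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "+", "-", "-"), region_type = "3UTR",
    start = c(1001L, 1501L, 2001L, 2501L),
    end = c(1100L, 1600L, 2100L, 2600L), stringsAsFactors = FALSE)
  ## spliced UTRs: P has 100+100 nt (plus), M has 100+100 nt (minus)
  sites <- data.frame(transcript_id = c("P", "M"), start = c(95L, 95L),
                      end = c(103L, 103L), site_type = "8mer",
                      site_seq = "", mirnas = "m", conserved = NA,
                      stringsAsFactors = FALSE)
  gg <- sitesToGenomic(sites, regions)
  ## every genomic base of each interval maps back into the footprint
  for (i in seq_len(nrow(gg))) {
    tx <- if (gg$chrom[i] == "chr1") "P" else "M"
    for (p in gg$start[i]:gg$end[i]) {
      off <- mapSnpToUtr(regions, tx, p)
      expect_true(off >= 95L && off < 103L)
    }
  }
  ## total genomic footprint equals the site length
  expect_equal(sum(gg$end - gg$start + 1L), 16L)
})
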