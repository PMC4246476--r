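test_that("goEnrich equals exhaustive draw enumeration", {
  ## N = 10 genes, K = 5 annotated, query of 2 fully annotated:
  ## P(X >= 2) = C(5,2)/C(10,2) = 10/45
  genes <- sprintf("g%02d", 1:10)
  ann <- data.frame(gene = genes[1:5], term = "T1",
                    stringsAsFactors = FALSE)
  r <- goEnrich(genes[1:2], ann, genes)
  expect_equal(r$p, 10 / 45)
  expect_equal(r$p, oracleHyperGe(10L, 5L, 2L, 2L))
  expect_equal(c(r$k, r$K, r$n, r$N), c(2L, 5L, 2L, 10L))

  ## random small configurations against the enumeration oracle
  set.seed(21)
  for (i in 1:20) {
    N <- sample(6:12, 1L); K <- sample(1:N, 1L); n <- sample(1:N, 1L)
    genes <- sprintf("g%02d", seq_len(N))
    ann <- data.frame(gene = genes[seq_len(K)], term = "T1")
    query <- sample(genes, n)
    r <- goEnrich(query, ann, genes)
    k <- sum(query %in% genes[seq_len(K)])
    if (k == 0L) expect_equal(nrow(r), 0L)
    else expect_equal(r$p, oracleHyperGe(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("goEnrich edge behaviors: absent terms, certainty, empty query", {
  genes <- sprintf("g%d", 1:6)
  ann <- data.frame(gene = c("g1", "g2", "g4"), term = c("T1", "T1", "T2"))
  ## term with no query gene is absent from the output
  r <- goEnrich(c("g1", "g2"), ann, genes)
  expect_false("T2" %in% r$term)
  ## query == background -> every reported term has p = 1
  r2 <- goEnrich(genes, ann, genes)
  expect_true(all(r2$p == 1))
  expect_warning(r3 <- goEnrich(character(0), ann, genes), "empty query")
  expect_equal(nrow(r3), 0L)
})

test_that("overlapTest matches subset enumeration and handles disjoint sets", {
  ## universe of 4 terms, both sets {t1,t2}: P(overlap 2) = 1/C(4,2)
  u <- c("t1", "t2", "t3", "t4")
  r <- overlapTest(c("t1", "t2"), c("t1", "t2"), u)
  expect_equal(sort(r$overlap), c("t1", "t2"))
  expect_equal(r$fisher_p, 1 / 6)
  ## enumeration oracle: draws of 2 from 4 with 2 marked
  expect_equal(r$fisher_p, oracleHyperGe(4L, 2L, 2L, 2L))
  r2 <- overlapTest(c("t1", "t2"), c("t3", "t4"), u)
  expect_equal(length(r2$overlap), 0L)
  expect_equal(r2$fisher_p, 1)
  expect_error(overlapTest("t1", "t1", character(0)), "empty term universe")
  expect_error(overlapTest("tX", "t1", u), "subsets")
})

test_that("selectCandidates applies both the p and the context rule", {
  asn <- data.frame(snp_id = c("s1", "s2", "s3"), dataset = "ds1",
                    inherited_p = c(0.005, 0.005, 0.02), n_proxies = 1L,
                    proxies = "x", stringsAsFactors = FALSE)
  sg <- data.frame(snp_id = c("s1", "s2", "s3"),
                   gene_symbol = c("gA", "gB", "gA"),
                   stringsAsFactors = FALSE)
  ann <- data.frame(gene = c("gA", "gC"), term = c("T1", "T1"))
  cand <- selectCandidates(asn, sg, "T1", ann, pSnp = 0.01)
  expect_equal(cand$snp_id, "s1")       # s2: no context; s3: p too large
  expect_equal(cand$terms, "T1")

  ## monotone in the p threshold: relaxing never removes a candidate
  set.seed(33)
  asn2 <- data.frame(snp_id = sprintf("s%02d", 1:40), dataset = "ds1",
                     inherited_p = runif(40), n_proxies = 1L, proxies = "x")
  sg2 <- data.frame(snp_id = asn2$snp_id,
                    gene_symbol = sample(c("gA", "gB", "gC"), 40L, TRUE))
  prev <- character(0)
  for (thr in c(0.001, 0.01, 0.1, 1)) {
    cur <- selectCandidates(asn2, sg2, "T1", ann, pSnp = thr)$snp_id
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("contextSelect wires enrichment, overlap and selection together", {
  set.seed(44)
  genes <- sprintf("g%03d", 1:60)
  ## pathway terms annotate a block of genes; disease genes overlap it
  ann <- rbind(
    data.frame(gene = genes[1:12], term = "PATH"),
    data.frame(gene = sample(genes, 60L, TRUE),
               term = sample(sprintf("T%02d", 1:20), 60L, TRUE)))
  asn <- data.frame(snp_id = sprintf("s%02d", 1:10), dataset = "ds1",
                    inherited_p = c(rep(0.002, 8L), 0.5, 0.5),
                    n_proxies = 1L, proxies = "x")
  sg <- data.frame(snp_id = asn$snp_id, gene_symbol = genes[1:10])
  res <- contextSelect(asn, sg, diseaseGenes = genes[5:16],
                       annotations = ann, backgroundGenes = genes)
  expect_true("PATH" %in% res$overlap$overlap)
  expect_true(all(res$candidates$inherited_p <= 0.01))
  expect_true(all(res$candidates$gene_symbol %in%
                    ann$gene[ann$term %in% res$overlap$overlap]))
})
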