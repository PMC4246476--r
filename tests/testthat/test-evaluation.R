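test_that("evaluation reproduces the published sensitivity and precision", {
  universe <- sprintf("u%05d", 1:12892)
  positives <- universe[1:368]
  ## 27 of the 286 selected SNPs are positives
  selected <- c(universe[1:27], universe[369:627])
  r <- evaluateCandidates(selected, positives, universe)
  expect_equal(r$n_hits, 27L)
  expect_equal(r$sensitivity, 27 / 368)
  expect_equal(r$precision, 27 / 286)
  expect_equal(round(r$sensitivity, 3), 0.073)
  expect_equal(round(r$precision, 3), 0.094)
  expect_equal(r$hyper_p,
               phyper(26, 368, 12892 - 368, 286, lower.tail = FALSE))

  ## multiple-testing comparison: 2 positives among 13 selected
  r13 <- evaluateCandidates(c(universe[1:2], universe[700:710]),
                            positives, universe)
  expect_equal(r13$sensitivity, 2 / 368)
  expect_equal(r13$precision, 2 / 13)
  expect_equal(round(r13$sensitivity, 4), 0.0054)
  expect_equal(round(r13$precision, 2), 0.15)
})

test_that("hypergeometric tail equals the enumeration oracle", {
  ## N=10, K=5, n=2, hits >= 1: 1 - C(5,2)/C(10,2) = 7/9
  u <- sprintf("s%02d", 1:10)
  r <- evaluateCandidates(c(u[1], u[6]), u[1:5], u)
  expect_equal(r$hyper_p, 7 / 9)
  expect_equal(r$hyper_p, oracleHyperGe(10L, 5L, 2L, 1L))
  set.seed(19)
  for (i in 1:15) {
    N <- sample(5:12, 1L); K <- sample(1:N, 1L); n <- sample(1:N, 1L)
    u <- sprintf("s%02d", seq_len(N))
    sel <- sample(u, n)
    h <- sum(sel %in% u[seq_len(K)])
    r <- evaluateCandidates(sel, u[seq_len(K)], u)
    expect_equal(r$hyper_p, oracleHyperGe(N, K, n, h), tolerance = 1e-12)
  }
})

test_that("degenerate evaluations behave as documented", {
  u <- sprintf("s%d", 1:20)
  r <- evaluateCandidates(u[1:5], u[1:5], u)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$precision, 1)
  r0 <- evaluateCandidates(character(0), u[1:5], u)
  expect_true(r0$flagged)
  expect_true(is.na(r0$precision))
  expect_equal(r0$sensitivity, 0)
})

test_that("adding a non-positive to the selection lowers precision only", {
  u <- sprintf("s%d", 1:50)
  pos <- u[1:10]
  sel <- u[c(1:4, 20:25)]
  a <- evaluateCandidates(sel, pos, u)
  b <- evaluateCandidates(c(sel, u[40]), pos, u)
  expect_lt(b$precision, a$precision)
  expect_equal(b$sensitivity, a$sensitivity)
})

test_that("per-type precision counts positives once per site type", {
  pos <- sprintf("p%03d", 1:368)
  hits <- pos[1:27]
  nh <- pos[28:368]
  sel <- c(hits, sprintf("x%03d", 1:259))
  typeMap <- rbind(
    data.frame(snp_id = c(hits[1:19], nh[1:146]), site_type = "7mer(2-8)"),
    data.frame(snp_id = c(hits[1:16], nh[1:185]), site_type = "7mer(1-7)"),
    data.frame(snp_id = c(hits[1:8], nh[1:101]), site_type = "8mer"),
    data.frame(snp_id = c(hits[1:3], nh[1:59]), site_type = "8mer-1a"))
  pt <- perTypePrecision(sel, pos, typeMap)
  get <- function(t, col) pt[pt$site_type == t, col]
  expect_equal(get("7mer(2-8)", "precision"), 19 / 165)
  expect_equal(round(get("7mer(2-8)", "precision"), 2), 0.12)
  expect_equal(get("7mer(1-7)", "precision"), 16 / 201)
  expect_equal(round(get("7mer(1-7)", "precision"), 3), 0.080)
  expect_equal(get("8mer", "precision"), 8 / 109)
  expect_equal(round(get("8mer", "precision"), 3), 0.073)
  expect_equal(get("8mer-1a", "precision"), 3 / 62)
  expect_equal(round(get("8mer-1a", "precision"), 3), 0.048)
  ## a type with no positive SNP is omitted; zero hits give 0
  pt0 <- perTypePrecision(character(0), pos[1:10],
                          data.frame(snp_id = pos[1:10],
                                     site_type = "8mer"))
  expect_equal(pt0$precision, 0)
  expect_equal(nrow(perTypePrecision("x", "p1",
                                     data.frame(snp_id = "q",
                                                site_type = "8mer"))), 0L)
})
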