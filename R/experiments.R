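## Replication experiments.
##
## Fixed, documented study designs used to verify the statistical
## behavior of the pipeline on synthetic data: planted-signal recovery,
## null calibration of the two Fisher tests, and the expected direction
## of the co-expression decile enrichment. The designs are frozen here so
## that tests and the acceptance script run the same experiment.

.expSeed <- function(seed, i) {
  as.integer((as.numeric(seed) + i * 7919) %% (.Machine$integer.max - 1L))
}

## study conditions for the planted-signal recovery experiment: 20 causal
## SNPs against a few thousand uniform-background seed-site SNPs; tight
## LD blocks keep the background uniform (wide blocks would hand causal
## p-values to non-causal block mates)
.recoveryConfig <- function(seed) {
  simConfig(seed = seed, n_genes = 500L, n_mirnas = 350L, n_snps = 12000L,
            n_causal = 20L, utr5_length = 50L, cds_length = 100L,
            n_disease_genes = 50L, ld_block_size = 2L,
            n_pathway_terms = 3L)
}

#' Planted-signal recovery experiment
#'
#' Repeatedly simulates a cohort with 20 planted causal seed-site SNPs
#' (causal association p-values from Beta(0.1, 1), background uniform,
#' causal host genes annotated to the disease pathway), runs the full
#' selection pipeline, and scores the context-based candidate set against
#' the planted truth. Recall is measured against the recoverable causal
#' set (those whose inherited p-value passes the 0.01 threshold), since
#' no selector can recover a causal SNP whose association signal never
#' reached nominal significance; precision is compared with the
#' context-free p <= 0.01 baseline.
#'
#' @param nReps number of replicates (default 20).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @return data.frame with one row per replicate: `recall` (of the
#'   recoverable causal set), `precision`, `baseline_precision`,
#'   `precision_ratio`, `n_assigned`, `n_recoverable`.
#' @export
recoveryExperiment <- function(nReps = 20L, seed = 1L) {
  out <- vector("list", nReps)
  for (i in seq_len(nReps)) {
    b <- simulateBundle(.recoveryConfig(.expSeed(seed, i)))
    res <- runPipeline(b, conservation = FALSE, energies = FALSE)
    a <- res$assignments
    causal <- b$truth$causal_snps
    base <- a$snp_id[a$inherited_p <= 0.01]
    recoverable <- intersect(causal, base)
    cand <- unique(res$candidates$snp_id)
    prec <- length(intersect(cand, causal)) / length(cand)
    bprec <- length(intersect(base, causal)) / length(base)
    out[[i]] <- data.frame(
      recall = length(intersect(cand, recoverable)) / length(recoverable),
      precision = prec, baseline_precision = bprec,
      precision_ratio = prec / bprec,
      n_assigned = nrow(a), n_recoverable = length(recoverable))
  }
  do.call(rbind, out)
}

#' Null calibration of the overlap and enrichment Fisher tests
#'
#' With no planted signal, the one-sided Fisher test on the overlap of
#' two independently enriched term lists and the two-sided Fisher test
#' attached to the nominal-significance enrichment odds ratio should both
#' reject at the nominal 5% level about 5% of the time. This experiment
#' draws fully null inputs (uniform p-values, random annotations) and
#' reports the realized rejection rates.
#'
#' @param nReps number of replicates (default 200).
#' @param seed master seed.
#' @return list with `overlap_rate`, `or_rate` and `n`.
#' @export
nullCalibration <- function(nReps = 200L, seed = 1L) {
  set.seed(.expSeed(seed, 0L))
  terms <- sprintf("GO:%04d", seq_len(1000L))
  genes <- sprintf("G%04d", seq_len(2000L))
  ov_sig <- or_sig <- logical(nReps)
  for (i in seq_len(nReps)) {
    ann <- data.frame(gene = rep(genes, each = 5L),
                      term = sample(terms, 10000L, replace = TRUE),
                      stringsAsFactors = FALSE)
    qe <- goEnrich(sample(genes, 200L), ann, genes)
    de <- goEnrich(sample(genes, 200L), ann, genes)
    ov <- overlapTest(qe$term[qe$enriched], de$term[de$enriched],
                      unique(ann$term))
    ov_sig[i] <- ov$fisher_p <= 0.05
    asn <- data.frame(snp_id = sprintf("s%d", 1:500), dataset = "ds1",
                      inherited_p = stats::runif(500), n_proxies = 1L,
                      proxies = sprintf("g%d", 1:500),
                      stringsAsFactors = FALSE)
    gwas <- data.frame(snp_id = c(sprintf("g%d", 1:500),
                                  sprintf("b%d", 1:3000)),
                       p = stats::runif(3500), stringsAsFactors = FALSE)
    or_sig[i] <- enrichmentOr(asn, gwas)$fisher_p <= 0.05
  }
  list(overlap_rate = mean(ov_sig), or_rate = mean(or_sig), n = nReps)
}

#' Direction of the co-expression decile enrichment
#'
#' Candidate-affected pairs draw correlations from Normal(-0.2, 0.15) and
#' the background from Normal(0.05, 0.2); the decile log-ratios should be
#' positive in negative-correlation intervals and negative in
#' positive-correlation intervals. Log-ratios are pooled across
#' replicates by interval sign.
#'
#' @param nReps number of replicates (default 20).
#' @param seed master seed.
#' @return list with `mean_neg` (mean log-ratio over intervals with upper
#'   bound < 0), `mean_pos` (over intervals with lower bound > 0) and the
#'   pooled counts `n_neg`, `n_pos`.
#' @export
coexprDirectionExperiment <- function(nReps = 20L, seed = 1L) {
  set.seed(.expSeed(seed, 0L))
  neg <- pos <- numeric(0)
  for (i in seq_len(nReps)) {
    cand <- pmin(1, pmax(-1, stats::rnorm(200L, -0.2, 0.15)))
    total <- pmin(1, pmax(-1, stats::rnorm(2000L, 0.05, 0.2)))
    d <- decileEnrichment(cand, total)
    ok <- !d$flagged & is.finite(d$log_ratio)
    neg <- c(neg, d$log_ratio[ok & d$high < 0])
    pos <- c(pos, d$log_ratio[ok & d$low > 0])
  }
  list(mean_neg = mean(neg), mean_pos = mean(pos),
       n_neg = length(neg), n_pos = length(pos))
}

#' Purifying-selection recovery from a simulated cohort
#'
#' Measures the realized common-SNP density ratio between the merged
#' seed-site footprint and the whole 3'UTR on a simulated bundle and
#' compares it with the planted multiplier.
#'
#' @param bundle a simulated bundle (its config carries the planted
#'   multiplier).
#' @return list with `ratio`, `target` (the planted multiplier),
#'   `mc_se` (Monte-Carlo standard error of the ratio from the two
#'   Poisson counts) and the underlying counts.
#' @export
purifyingRecovery <- function(bundle) {
  d <- regionDensity(bundle$snps, bundle$regions,
                     sitesToGenomic(bundle$truth$sites, bundle$regions))
  pick <- function(region) {
    r <- d[d$region == region & d$maf_class == "common", ]
    c(count = r$snp_count, density = r$density)
  }
  m <- pick("MRESS"); u <- pick("3UTR")
  ratio <- m[["density"]] / u[["density"]]
  se <- ratio * sqrt(1 / m[["count"]] + 1 / u[["count"]])
  list(ratio = ratio, target = bundle$config$mress_common_snp_multiplier,
       mc_se = se, mress_count = m[["count"]], utr3_count = u[["count"]])
}
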