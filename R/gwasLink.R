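#' Inherit GWAS p-values through linkage-disequilibrium proxies
#'
#' A seed-site SNP's proxies are the GWAS-genotyped SNPs in LD with it at
#' `D' >= dprimeMin` (strictly applied; the default 1.0 admits only
#' perfect D'), plus the SNP itself when it was genotyped. The inherited
#' p-value is the minimum over the proxy set; SNPs with no proxy are
#' absent from the output and counted in `attr(x, "n_unmapped")`.
#'
#' @param mressSnpIds character vector of seed-site SNP ids.
#' @param gwas data.frame with columns `snp_id`, `p`.
#' @param ldPairs data.frame with columns `snpA`, `snpB`, `dprime`, `r2`
#'   (symmetrized internally).
#' @param dprimeMin D' threshold in (0, 1] (default 1.0).
#' @param dataset label copied into the output (default "ds1").
#' @return data.frame with columns `snp_id`, `dataset`, `inherited_p`,
#'   `n_proxies`, `proxies` (comma-joined ids).
#' @export
assignPvalues <- function(mressSnpIds, gwas, ldPairs, dprimeMin = 1.0,
                          dataset = "ds1") {
  stopifnot(dprimeMin > 0, dprimeMin <= 1)
  mressSnpIds <- unique(mressSnpIds)
  ld <- rbind(
    data.frame(a = ldPairs$snpA, b = ldPairs$snpB, dprime = ldPairs$dprime,
               stringsAsFactors = FALSE),
    data.frame(a = ldPairs$snpB, b = ldPairs$snpA, dprime = ldPairs$dprime,
               stringsAsFactors = FALSE))
  ld <- ld[ld$dprime >= dprimeMin & ld$a %in% mressSnpIds &
             ld$b %in% gwas$snp_id, , drop = FALSE]
  links <- rbind(
    ld[, c("a", "b")],
    data.frame(a = intersect(mressSnpIds, gwas$snp_id),
               b = intersect(mressSnpIds, gwas$snp_id),
               stringsAsFactors = FALSE))
  links <- unique(links)
  attrn <- length(mressSnpIds) - length(unique(links$a))
  if (nrow(links) == 0L) {
    out <- data.frame(snp_id = character(0), dataset = character(0),
                      inherited_p = numeric(0), n_proxies = integer(0),
                      proxies = character(0), stringsAsFactors = FALSE)
    attr(out, "n_unmapped") <- attrn
    return(out)
  }
  links$p <- gwas$p[match(links$b, gwas$snp_id)]
  sp <- split(links, links$a)
  out <- data.frame(
    snp_id = names(sp),
    dataset = dataset,
    inherited_p = vapply(sp, function(d) min(d$p), numeric(1L)),
    n_proxies = vapply(sp, nrow, integer(1L)),
    proxies = vapply(sp, function(d)
      paste(sort(unique(d$b)), collapse = ","), character(1L)),
    stringsAsFactors = FALSE)
  out <- out[order(out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unmapped") <- attrn
  out
}

#' Quantile-quantile data for inherited p-values
#'
#' Observed p-values are sorted ascending (largest -log10 first against
#' the smallest expected quantile); expected quantiles for rank i of n are
#' (i - 0.5) / n. Both axes are -log10(p).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param pFloor values below this are capped with a warning (default
#'   1e-300).
#' @return data.frame with columns `expected`, `observed` (both -log10),
#'   ordered from the most significant observation (rank 1) downwards, so
#'   `expected` is strictly decreasing.
#' @export
qqData <- function(p, pFloor = 1e-300) {
  stopifnot(length(p) >= 1L)
  if (any(p < pFloor)) {
    warning(sprintf("%d p-value(s) below %g capped", sum(p < pFloor),
                    pFloor))
    p[p < pFloor] <- pFloor
  }
  n <- length(p)
  obs <- sort(-log10(p), decreasing = TRUE)
  exp_ <- -log10((seq_len(n) - 0.5) / n)
  data.frame(expected = exp_, observed = obs)
}

#' Enrichment odds ratio of seed-site SNPs among nominally significant
#' GWAS SNPs
#'
#' Builds the 2x2 table (seed-site SNPs vs background, p <= alpha vs
#' p > alpha) and computes the odds ratio (a*d)/(b*c) with a two-sided
#' Fisher exact p-value. The default background is GWAS SNPs not serving
#' as proxy for any seed-site SNP; `background = "all"` uses every GWAS
#' SNP instead.
#'
#' @param assignments output of [assignPvalues()].
#' @param gwas data.frame with columns `snp_id`, `p`.
#' @param alpha nominal significance threshold (default 0.05).
#' @param background `"unlinked"` (default) or `"all"`.
#' @return list with `table` (2x2 matrix), `odds_ratio`, `fisher_p`,
#'   `haldane` (TRUE when a zero cell forced the +0.5 correction).
#' @export
enrichmentOr <- function(assignments, gwas, alpha = 0.05,
                         background = c("unlinked", "all")) {
  background <- match.arg(background)
  proxy_ids <- unique(unlist(strsplit(assignments$proxies, ",",
                                      fixed = TRUE)))
  bg <- if (background == "unlinked")
    gwas[!(gwas$snp_id %in% proxy_ids), , drop = FALSE] else gwas
  a <- sum(assignments$inherited_p <= alpha)
  b <- nrow(assignments) - a
  c_ <- sum(bg$p <= alpha)
  d <- nrow(bg) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2L,
                dimnames = list(c("p<=alpha", "p>alpha"),
                                c("mress", "background")))
  haldane <- any(tab == 0L)
  or <- if (haldane) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
        else (a * d) / (b * c_)
  fp <- stats::fisher.test(tab)$p.value
  list(table = tab, odds_ratio = or, fisher_p = fp, haldane = haldane)
}
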