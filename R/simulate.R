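## Synthetic-data generator.
##
## Emulates every input the pipeline consumes -- microRNA and 3'UTR
## sequences with a genomic layout, a SNP table under purifying selection
## on seed sites, GWAS p-values with planted causal signal spread over LD
## blocks, GO annotations sharing pathway terms between causal hosts and
## disease genes, co-expression correlations, mouse orthologs, trilateral
## input tables and a known-positive list -- together with ground truth
## for recovery testing.

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator with defaults sized for a
#' full pipeline run in well under two minutes on one CPU.
#'
#' @param seed integer seed governing all randomness.
#' @param n_genes,n_mirnas,n_snps problem size (defaults 2000 / 200 /
#'   50000).
#' @param utr_length_range 3'UTR length range in nt (default 200-1500).
#' @param utr5_length,cds_length fixed lengths of the other regions.
#' @param prop_minus fraction of minus-strand transcripts (default 0.3).
#' @param mress_common_snp_multiplier purifying-selection multiplier in
#'   (0, 1]: the planted ratio of common-SNP density in seed sites over
#'   the whole 3'UTR (default 0.5).
#' @param maf_common_frac baseline probability that a frequency-known SNP
#'   is common (default 0.5).
#' @param frac_unknown_maf fraction of SNPs lacking usable frequency data
#'   (default 0.1).
#' @param frac_causal fraction of seed-site SNPs planted as causal
#'   (default 0.01); overridden by `n_causal`.
#' @param n_causal explicit number of planted causal SNPs, or NULL.
#' @param causal_p_shape Beta(a, b) parameters for causal association
#'   p-values (default c(0.1, 1)); the background is Uniform(0, 1).
#' @param ld_block_size SNPs per LD block (default 5).
#' @param dprime_within_block,r2_within_block pairwise LD inside a block
#'   (defaults 1.0 and 0.9).
#' @param frac_genotyped fraction of SNPs present in the GWAS table
#'   (default 0.6).
#' @param go_terms,terms_per_gene GO vocabulary size and annotations per
#'   gene (defaults 100 and 5).
#' @param n_pathway_terms disease-pathway terms shared between causal
#'   hosts and disease genes (default 5).
#' @param disease_term_overlap probability that a disease gene's
#'   annotation is drawn from the pathway terms (default 0.5).
#' @param n_disease_genes size of the disease gene list (default 100).
#' @param coexpr_true,coexpr_null Normal(mean, sd) for correlations of
#'   causally affected vs other pairs (defaults c(-0.2, 0.15) and
#'   c(0.05, 0.2)).
#' @param n_coexpr_pairs co-expression table size (default 5000).
#' @param mouse_divergence per-base substitution rate for the mouse
#'   ortholog outside protected sites (default 0.1).
#' @param conserved_frac fraction of sites protected from divergence
#'   (default 0.5).
#' @param n_diseases disease vocabulary size (default 10).
#' @param n_validated validated microRNA-gene interactions (default 500).
#' @param positives_recall fraction of causal SNPs included in the
#'   known-positive list (default 0.8).
#' @param positives_noise unrelated seed-site SNPs added to the positive
#'   list (default 2).
#' @return named list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L, n_genes = 2000L, n_mirnas = 200L,
                      n_snps = 50000L, utr_length_range = c(200L, 1500L),
                      utr5_length = 150L, cds_length = 900L,
                      prop_minus = 0.3,
                      mress_common_snp_multiplier = 0.5,
                      maf_common_frac = 0.5, frac_unknown_maf = 0.1,
                      frac_causal = 0.01, n_causal = NULL,
                      causal_p_shape = c(0.1, 1),
                      ld_block_size = 5L, dprime_within_block = 1.0,
                      r2_within_block = 0.9, frac_genotyped = 0.6,
                      go_terms = 100L, terms_per_gene = 3L,
                      n_pathway_terms = 5L, disease_term_overlap = 0.5,
                      n_disease_genes = 100L,
                      coexpr_true = c(-0.2, 0.15),
                      coexpr_null = c(0.05, 0.2),
                      n_coexpr_pairs = 5000L,
                      mouse_divergence = 0.1, conserved_frac = 0.5,
                      n_diseases = 10L, n_validated = 500L,
                      positives_recall = 0.8, positives_noise = 2L) {
  cfg <- as.list(environment())
  stopifnot(cfg$mress_common_snp_multiplier > 0,
            cfg$mress_common_snp_multiplier <= 1,
            cfg$frac_causal >= 0, cfg$frac_causal <= 1,
            cfg$frac_genotyped > 0, cfg$frac_genotyped <= 1,
            cfg$ld_block_size >= 1L,
            length(cfg$causal_p_shape) == 2L, all(cfg$causal_p_shape > 0),
            cfg$mouse_divergence >= 0, cfg$mouse_divergence <= 1)
  class(cfg) <- "simConfig"
  cfg
}

.randRna <- function(n, len) {
  vapply(len, function(l)
    paste(sample(c("A", "C", "G", "U"), l, replace = TRUE), collapse = ""),
    character(1L))
}

#' Generate a complete synthetic input bundle
#'
#' @param config a [simConfig()] list.
#' @return named list with elements `mirnas`, `transcripts`, `regions`,
#'   `snps`, `gwas`, `ld`, `go`, `disease_genes`, `coexpr`,
#'   `mirna_gene`, `mirna_disease`, `gene_disease`, `positives`,
#'   `mouse_utr3`, `truth` (ground-truth list) and `config`.
#' @export
simulateBundle <- function(config = simConfig()) {
  stopifnot(inherits(config, "simConfig"))
  set.seed(config$seed)
  chroms <- c(paste0("chr", 1:22), "chrX")

  ## microRNAs
  mirna_ids <- sprintf("hsa-mir-%04d", seq_len(config$n_mirnas))
  mirnas <- stats::setNames(.randRna(config$n_mirnas,
                                     rep(22L, config$n_mirnas)), mirna_ids)

  ## transcripts and genomic layout (one block per region, transcripts
  ## tiled along each chromosome with 1 kb gaps)
  ng <- config$n_genes
  gene <- sprintf("GENE%05d", seq_len(ng))
  txid <- sprintf("NM_%06d", seq_len(ng))
  chrom <- sample(chroms, ng, replace = TRUE)
  strand <- ifelse(stats::runif(ng) < config$prop_minus, "-", "+")
  u3len <- sample(config$utr_length_range[1L]:config$utr_length_range[2L],
                  ng, replace = TRUE)
  u5len <- rep(config$utr5_length, ng)
  cdlen <- rep(config$cds_length, ng)
  txlen <- u5len + cdlen + u3len
  start <- integer(ng)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    start[i] <- cumsum(c(1L, utils::head(txlen[i] + 1000L, -1L)))
  }
  ## 5'->3' order of region blocks along the genome depends on strand
  plus <- strand == "+"
  len1 <- ifelse(plus, u5len, u3len)
  len2 <- cdlen
  len3 <- ifelse(plus, u3len, u5len)
  typ1 <- ifelse(plus, "5UTR", "3UTR")
  typ3 <- ifelse(plus, "3UTR", "5UTR")
  e1 <- start + len1 - 1L
  e2 <- e1 + len2
  e3 <- e2 + len3
  regions <- data.frame(
    transcript_id = rep(txid, 3L), gene_symbol = rep(gene, 3L),
    chrom = rep(chrom, 3L), strand = rep(strand, 3L),
    region_type = c(typ1, rep("CDS", ng), typ3),
    start = c(start, e1 + 1L, e2 + 1L),
    end = c(e1, e2, e3), stringsAsFactors = FALSE)
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  utr3 <- stats::setNames(.randRna(ng, u3len), txid)
  transcripts <- data.frame(transcript_id = txid, gene_symbol = gene,
                            chrom = chrom, strand = strand, utr3 = utr3,
                            stringsAsFactors = FALSE)

  ## seed sites on the reference UTRs, and their genomic footprint
  groups <- extractSeeds(mirnas)
  sites <- scanSites(utr3, groups)
  mress_genomic <- sitesToGenomic(sites, regions)
  mress_gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    mress_genomic$chrom,
    IRanges::IRanges(mress_genomic$start, mress_genomic$end)))

  ## SNPs sampled uniformly over the mRNA footprint
  rw <- regions$end - regions$start + 1L
  ri <- sample(nrow(regions), config$n_snps, replace = TRUE, prob = rw)
  off <- floor(stats::runif(config$n_snps) * rw[ri])
  pos <- regions$start[ri] + as.integer(off)
  dup <- duplicated(paste(regions$chrom[ri], pos))
  ri <- ri[!dup]; pos <- pos[!dup]
  ns <- length(pos)
  snp_id <- sprintf("rs%07d", seq_len(ns))
  ## reference allele: sequence base for 3'UTR SNPs, random elsewhere
  is_u3 <- regions$region_type[ri] == "3UTR"
  sense_off <- ifelse(regions$strand[ri] == "+",
                      pos - regions$start[ri], regions$end[ri] - pos)
  ## minus-strand transcripts list 3UTR first genomically, so the block
  ## offset is also the spliced offset (single-block regions)
  ref <- ifelse(is_u3,
                chartr("U", "T", substr(utr3[match(regions$transcript_id[ri],
                                                   txid)],
                                        sense_off + 1L, sense_off + 1L)),
                sample(c("A", "C", "G", "T"), ns, replace = TRUE))
  minus <- regions$strand[ri] == "-"
  ref[is_u3 & minus] <- .compDna(ref[is_u3 & minus])
  bases <- c("A", "C", "G", "T")
  alt <- bases[(match(ref, bases) - 1L + sample(3L, ns, replace = TRUE)) %%
                 4L + 1L]

  ## purifying selection: common-SNP rate inside the merged seed-site
  ## footprint is scaled so the MRESS/3'UTR common-density ratio equals
  ## the configured multiplier in expectation
  sp_gr <- GenomicRanges::GRanges(regions$chrom[ri],
                                  IRanges::IRanges(pos, pos))
  in_mress <- GenomicRanges::countOverlaps(sp_gr, mress_gr) > 0L
  u3_gr <- .regionRanges(regions[regions$region_type == "3UTR", ])
  f_m <- sum(GenomicRanges::width(mress_gr)) /
    sum(GenomicRanges::width(u3_gr))
  m <- config$mress_common_snp_multiplier
  q_non <- config$maf_common_frac
  q_mress <- min(1, m * (1 - f_m) * q_non / (1 - m * f_m))
  p_common <- ifelse(in_mress, q_mress, q_non)
  unknown <- stats::runif(ns) < config$frac_unknown_maf
  common <- !unknown & stats::runif(ns) < p_common
  maf <- rep(NA_real_, ns)
  maf[common] <- stats::runif(sum(common), 0.01, 0.5)
  maf[!common & !unknown] <- stats::runif(sum(!common & !unknown),
                                          0.001, 0.0099)
  half <- unknown & stats::runif(ns) < 0.5
  maf[half] <- stats::runif(sum(half), 0.001, 0.5)
  n_chrom <- ifelse(unknown, sample(2:98, ns, replace = TRUE),
                    sample(100:2000, ns, replace = TRUE))
  snps <- data.frame(snp_id = snp_id, chrom = regions$chrom[ri], pos = pos,
                     ref_allele = ref, alt_allele = alt, maf = maf,
                     n_chromosomes = as.integer(n_chrom),
                     stringsAsFactors = FALSE)

  ## causal SNPs: seed-site SNPs in the 3'UTR
  mress_snp_i <- which(in_mress & is_u3)
  n_causal <- if (!is.null(config$n_causal)) config$n_causal
              else round(config$frac_causal * length(mress_snp_i))
  if (n_causal > length(mress_snp_i))
    stop(sprintf("infeasible config: %d causal SNPs requested but only %d seed-site SNPs generated",
                 n_causal, length(mress_snp_i)))
  causal_i <- sort(sample(mress_snp_i, n_causal))
  causal_ids <- snp_id[causal_i]
  causal_genes <- unique(regions$gene_symbol[ri[causal_i]])

  ## GO annotations with a planted disease pathway
  terms <- sprintf("GO:%07d", seq_len(config$go_terms))
  pathway <- sample(terms, config$n_pathway_terms)
  go <- data.frame(
    gene = rep(gene, each = config$terms_per_gene),
    term = sample(terms, ng * config$terms_per_gene, replace = TRUE),
    stringsAsFactors = FALSE)
  ## context concordance: causal host genes are annotated to the whole
  ## disease pathway
  if (length(causal_genes))
    go <- rbind(go, data.frame(
      gene = rep(causal_genes, each = length(pathway)),
      term = rep(pathway, length(causal_genes)),
      stringsAsFactors = FALSE))
  disease_gene_set <- sample(gene, min(config$n_disease_genes, ng))
  dg_terms <- lapply(disease_gene_set, function(g) {
    from_path <- stats::runif(config$terms_per_gene) <
      config$disease_term_overlap
    out <- character(config$terms_per_gene)
    out[from_path] <- sample(pathway, sum(from_path), replace = TRUE)
    out[!from_path] <- sample(terms, sum(!from_path), replace = TRUE)
    out
  })
  go <- rbind(go, data.frame(
    gene = rep(disease_gene_set, each = config$terms_per_gene),
    term = unlist(dg_terms), stringsAsFactors = FALSE))
  go <- unique(go)

  ## LD blocks of consecutive SNPs and the GWAS table; causal signal is a
  ## property of the locus, so every genotyped SNP in a causal block
  ## draws its p-value from the causal Beta distribution
  ord <- order(snps$chrom, snps$pos)
  block <- integer(ns)
  block[ord] <- (seq_len(ns) - 1L) %/% config$ld_block_size + 1L
  genotyped <- stats::runif(ns) < config$frac_genotyped
  causal_blocks <- unique(block[causal_i])
  for (b in causal_blocks) {
    mem <- which(block == b)
    if (!any(genotyped[mem]))
      genotyped[sample(mem, 1L)] <- TRUE
  }
  p <- stats::runif(ns)
  in_causal_block <- block %in% causal_blocks
  p[in_causal_block] <- stats::rbeta(sum(in_causal_block),
                                     config$causal_p_shape[1L],
                                     config$causal_p_shape[2L])
  p <- pmin(pmax(p, 1e-300), 1)
  gwas <- data.frame(snp_id = snp_id[genotyped], p = p[genotyped],
                     stringsAsFactors = FALSE)
  ld <- do.call(rbind, lapply(split(snp_id, block), function(ids) {
    if (length(ids) < 2L) return(NULL)
    cb <- utils::combn(sort(ids), 2L)
    data.frame(snpA = cb[1L, ], snpB = cb[2L, ],
               dprime = config$dprime_within_block,
               r2 = config$r2_within_block, stringsAsFactors = FALSE)
  }))
  rownames(ld) <- NULL

  ## mouse orthologs: per-base divergence, protected conserved sites
  protect_site <- stats::runif(nrow(sites)) < config$conserved_frac
  ## planted causal sites are always conserved: the causal signal lives
  ## in functional (conserved) seed sites by construction
  if (length(causal_i)) {
    ctx_ <- regions$transcript_id[ri[causal_i]]
    coff <- sense_off[causal_i]
    for (k in seq_along(causal_i))
      protect_site <- protect_site |
        (sites$transcript_id == ctx_[k] & sites$start <= coff[k] &
           coff[k] < sites$end)
  }
  prot <- split(sites[protect_site, c("start", "end")],
                sites$transcript_id[protect_site])
  rbases <- c("A", "C", "G", "U")
  mouse_utr3 <- utr3
  for (i in seq_len(ng)) {
    s <- strsplit(utr3[[i]], "")[[1L]]
    hit <- stats::runif(length(s)) < config$mouse_divergence
    ps <- prot[[txid[i]]]
    if (!is.null(ps) && nrow(ps))
      hit[unlist(mapply(seq, ps$start + 1L, ps$end,
                        SIMPLIFY = FALSE))] <- FALSE
    if (any(hit))
      s[hit] <- rbases[(match(s[hit], rbases) - 1L +
                          sample(3L, sum(hit), replace = TRUE)) %% 4L + 1L]
    mouse_utr3[[i]] <- paste(s, collapse = "")
  }

  ## microRNA-gene-disease inputs and co-expression
  site_pairs <- unique(data.frame(
    mirna_id = unlist(strsplit(sites$mirnas, ",", fixed = TRUE)),
    gene = transcripts$gene_symbol[match(
      rep(sites$transcript_id, lengths(strsplit(sites$mirnas, ","))),
      txid)],
    stringsAsFactors = FALSE))
  nv <- min(config$n_validated, nrow(site_pairs))
  mirna_gene <- site_pairs[sample(nrow(site_pairs), nv), , drop = FALSE]
  diseases <- sprintf("disease_%02d", seq_len(config$n_diseases))
  shared <- mirna_gene[sample(nrow(mirna_gene),
                              ceiling(0.3 * nrow(mirna_gene))), ,
                       drop = FALSE]
  shared$disease <- sample(diseases, nrow(shared), replace = TRUE)
  mirna_disease <- unique(rbind(
    shared[, c("mirna_id", "disease")],
    data.frame(mirna_id = sample(mirna_ids, config$n_mirnas %/% 2L),
               disease = sample(diseases, config$n_mirnas %/% 2L,
                                replace = TRUE),
               stringsAsFactors = FALSE)))
  gene_disease <- unique(rbind(
    shared[, c("gene", "disease")],
    data.frame(gene = sample(gene, ng %/% 10L),
               disease = sample(diseases, ng %/% 10L, replace = TRUE),
               stringsAsFactors = FALSE)))

  ## causally affected pairs draw negative correlations
  causal_tx <- unique(regions$transcript_id[ri[causal_i]])
  csites <- sites[sites$transcript_id %in% causal_tx, , drop = FALSE]
  true_pairs <- unique(data.frame(
    mirna_id = unlist(strsplit(csites$mirnas, ",", fixed = TRUE)),
    gene = transcripts$gene_symbol[match(
      rep(csites$transcript_id, lengths(strsplit(csites$mirnas, ","))),
      txid)],
    stringsAsFactors = FALSE))
  n_null <- max(0L, config$n_coexpr_pairs - nrow(true_pairs))
  null_pool <- site_pairs[sample(nrow(site_pairs),
                                 min(n_null, nrow(site_pairs))), ,
                          drop = FALSE]
  coexpr <- rbind(
    if (nrow(true_pairs))
      data.frame(true_pairs,
                 r = stats::rnorm(nrow(true_pairs), config$coexpr_true[1L],
                                  config$coexpr_true[2L]),
                 stringsAsFactors = FALSE),
    data.frame(null_pool,
               r = stats::rnorm(nrow(null_pool), config$coexpr_null[1L],
                                config$coexpr_null[2L]),
               stringsAsFactors = FALSE))
  coexpr <- coexpr[!duplicated(coexpr[, c("mirna_id", "gene")]), ,
                   drop = FALSE]
  coexpr$r <- pmin(1, pmax(-1, coexpr$r))
  rownames(coexpr) <- NULL

  ## known positives: most causal SNPs plus a little noise
  pos_ids <- causal_ids[stats::runif(length(causal_ids)) <
                          config$positives_recall]
  noise_pool <- setdiff(snp_id[mress_snp_i], causal_ids)
  if (length(noise_pool) && config$positives_noise > 0L)
    pos_ids <- c(pos_ids, sample(noise_pool,
                                 min(config$positives_noise,
                                     length(noise_pool))))
  positives <- sort(unique(pos_ids))

  truth <- list(
    causal_snps = causal_ids,
    causal_genes = causal_genes,
    pathway_terms = sort(pathway),
    sites = sites,
    conserved_sites = sites[protect_site, , drop = FALSE],
    true_pairs = true_pairs,
    mress_snp_ids = snp_id[mress_snp_i],
    f_mress_of_utr3 = f_m)

  list(mirnas = mirnas, transcripts = transcripts, regions = regions,
       snps = snps, gwas = gwas, ld = ld, go = go,
       disease_genes = list(ds1 = disease_gene_set), coexpr = coexpr,
       mirna_gene = mirna_gene, mirna_disease = mirna_disease,
       gene_disease = gene_disease, positives = positives,
       mouse_utr3 = mouse_utr3, truth = truth, config = config)
}

#' Write a simulated bundle to disk in the package's file dialects
#'
#' @param bundle list from [simulateBundle()].
#' @param dir output directory (created if needed); ground truth goes
#'   under `dir/truth/`.
#' @return invisibly, `dir`.
#' @export
writeBundle <- function(bundle, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE,
             showWarnings = FALSE)
  wfa <- function(x, file) {
    Biostrings::writeXStringSet(Biostrings::RNAStringSet(x),
                                file.path(dir, file))
  }
  wtsv <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wfa(bundle$mirnas, "mirna.fa")
  wfa(bundle$transcripts$utr3 |>
        stats::setNames(bundle$transcripts$transcript_id), "utr3.fa")
  wfa(bundle$mouse_utr3, "mouse_utr3.fa")
  wtsv(bundle$regions, "regions.tsv")
  wtsv(bundle$snps, "snps.tsv")
  wtsv(bundle$gwas, "gwas.tsv")
  wtsv(bundle$ld, "ld.tsv")
  wtsv(bundle$go, "go.tsv")
  wtsv(data.frame(dataset = rep(names(bundle$disease_genes),
                                lengths(bundle$disease_genes)),
                  gene = unlist(bundle$disease_genes)), "disease_genes.tsv")
  wtsv(bundle$coexpr, "coexpr.tsv")
  wtsv(bundle$mirna_gene, "mirna_gene.tsv")
  wtsv(bundle$mirna_disease, "mirna_disease.tsv")
  wtsv(bundle$gene_disease, "gene_disease.tsv")
  writeLines(bundle$positives, file.path(dir, "positives.txt"))
  writeLines(bundle$truth$causal_snps,
             file.path(dir, "truth", "causal_snps.txt"))
  writeLines(bundle$truth$pathway_terms,
             file.path(dir, "truth", "pathway_terms.txt"))
  wtsv(bundle$truth$sites, file.path("truth", "sites.tsv"))
  wtsv(bundle$truth$true_pairs, file.path("truth", "true_pairs.tsv"))
  invisible(dir)
}

#' Compare pipeline output with simulation ground truth
#'
#' @param candidateSnps character vector of candidate SNP ids from the
#'   pipeline.
#' @param truth ground-truth list from a simulated bundle (needs element
#'   `causal_snps`).
#' @return list with `recall`, `precision` (NA and `flagged = TRUE` for an
#'   empty candidate set), `n_causal`, `n_candidates`, `n_recovered`.
#' @export
truthCompare <- function(candidateSnps, truth) {
  candidateSnps <- unique(candidateSnps)
  causal <- unique(truth$causal_snps)
  hit <- intersect(candidateSnps, causal)
  list(recall = if (length(causal)) length(hit) / length(causal)
                else NA_real_,
       precision = if (length(candidateSnps))
         length(hit) / length(candidateSnps) else NA_real_,
       n_causal = length(causal), n_candidates = length(candidateSnps),
       n_recovered = length(hit),
       flagged = length(candidateSnps) == 0L)
}
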