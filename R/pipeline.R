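#' Run the full candidate-selection pipeline on an input bundle
#'
#' Executes every stage in order: seed extraction, reference site scan,
#' allele-aware create/loss calling, optional conservation filtering,
#' LD-proxy p-value inheritance, QQ data, nominal-significance enrichment
#' odds ratio, GO-context candidate selection, evaluation against the
#' known-positive list, SNP-density table, trilateral interactions,
#' co-expression decile enrichment and (optionally) duplex energetics
#' with haplotype scores.
#'
#' @param bundle input list as produced by [simulateBundle()] (or
#'   assembled from the readers in this package: elements `mirnas`,
#'   `transcripts`, `regions`, `snps`, `gwas`, `ld`, `go`,
#'   `disease_genes`, `coexpr`, `mirna_gene`, `mirna_disease`,
#'   `gene_disease`, `positives`, optionally `mouse_utr3`).
#' @param config parameter list from [defaultConfig()] /
#'   [readPipelineConfig()].
#' @param conservation apply the human-mouse conservation filter to the
#'   allelic effects (default TRUE when `bundle$mouse_utr3` is present).
#' @param energies compute the nearest-neighbor energy table for the
#'   effects of GWAS-mapped SNPs (default TRUE).
#' @param dataset dataset label for the GWAS stage (default "ds1").
#' @return named list with the outputs of every stage: `groups`, `sites`,
#'   `effects`, `assignments`, `qq`, `enrichment_or`, `context`
#'   (list from [contextSelect()]), `candidates`, `evaluation`,
#'   `density`, `trilateral`, `perturbing`, `coexpr_enrichment`,
#'   `energies`, `snp_deltas`, `haplotypes`.
#' @export
runPipeline <- function(bundle, config = defaultConfig(),
                        conservation = !is.null(bundle$mouse_utr3),
                        energies = TRUE, dataset = "ds1") {
  groups <- extractSeeds(bundle$mirnas)
  utrs <- stats::setNames(bundle$transcripts$utr3,
                          bundle$transcripts$transcript_id)
  sites <- scanSites(utrs, groups)
  effects <- scanAllelicEffects(bundle$transcripts, bundle$regions,
                                bundle$snps, groups,
                                flank = config$flank)

  if (conservation && nrow(effects)) {
    ## conservation is judged on the reference-sequence footprint; the
    ## SNP position itself is excused from base identity (for created
    ## sites that base does not exist in the reference)
    fp <- unique(effects[, c("transcript_id", "site_start", "site_end")])
    fp_sites <- data.frame(transcript_id = fp$transcript_id,
                           start = fp$site_start, end = fp$site_end,
                           site_type = "footprint", site_seq = "",
                           mirnas = "", conserved = NA,
                           stringsAsFactors = FALSE)
    snp_pos0 <- unique(do.call(rbind, lapply(
      unique(effects$transcript_id), function(tx) {
        sid <- unique(effects$snp_id[effects$transcript_id == tx])
        si <- match(sid, bundle$snps$snp_id)
        data.frame(transcript_id = tx,
                   pos = vapply(bundle$snps$pos[si], function(p)
                     mapSnpToUtr(bundle$regions, tx, p), integer(1L)),
                   stringsAsFactors = FALSE)
      })))
    maps <- .conservationMaps(utrs, .normalizeRna(bundle$mouse_utr3),
                              unique(c(fp_sites$transcript_id,
                                       sites$transcript_id)),
                              gapOpen = config$gap_open,
                              gapExtend = config$gap_extend)
    flagged <- conservationFilter(fp_sites, utrs, bundle$mouse_utr3,
                                  gapOpen = config$gap_open,
                                  gapExtend = config$gap_extend,
                                  exempt = snp_pos0, maps = maps)
    key <- paste(flagged$transcript_id, flagged$start, flagged$end)
    conserved <- flagged$conserved[match(
      paste(effects$transcript_id, effects$site_start, effects$site_end),
      key)]
    effects <- effects[conserved, , drop = FALSE]
    sites <- conservationFilter(sites, utrs, bundle$mouse_utr3,
                                gapOpen = config$gap_open,
                                gapExtend = config$gap_extend,
                                maps = maps)
  }

  mress_ids <- unique(effects$snp_id)
  assignments <- assignPvalues(mress_ids, bundle$gwas, bundle$ld,
                               dprimeMin = config$dprime_min,
                               dataset = dataset)
  qq <- if (nrow(assignments)) qqData(assignments$inherited_p) else NULL
  eor <- if (nrow(assignments))
    enrichmentOr(assignments, bundle$gwas) else NULL

  snp_genes <- unique(effects[, c("snp_id", "gene_symbol")])
  background <- unique(bundle$go$gene)
  ctx <- contextSelect(assignments, snp_genes,
                       bundle$disease_genes[[dataset]], bundle$go,
                       background, pSnp = config$p_snp,
                       pGo = config$p_go)
  candidates <- ctx$candidates

  type_map <- unique(effects[, c("snp_id", "site_type")])
  evaluation <- if (nrow(assignments)) {
    universe <- assignments$snp_id
    evaluateCandidates(intersect(unique(candidates$snp_id), universe),
                       intersect(bundle$positives, universe), universe,
                       typeMap = type_map)
  } else NULL

  density <- regionDensity(bundle$snps, bundle$regions,
                           sitesToGenomic(sites, bundle$regions),
                           commonThreshold = config$maf_common,
                           minChromosomes = config$min_chromosomes)

  tri <- buildTrilateral(bundle$mirna_gene, bundle$mirna_disease,
                         bundle$gene_disease)
  perturbing <- snpsPerturbing(tri, effects)

  ## co-expression: pairs affected by candidate SNPs vs the total table
  cand_eff <- effects[effects$snp_id %in% candidates$snp_id, ,
                      drop = FALSE]
  ce <- NULL
  if (nrow(cand_eff)) {
    ml <- strsplit(cand_eff$mirnas, ",", fixed = TRUE)
    cp <- unique(data.frame(
      mirna_id = unlist(ml),
      gene = rep(cand_eff$gene_symbol, lengths(ml)),
      stringsAsFactors = FALSE))
    cr <- merge(cp, bundle$coexpr, by = c("mirna_id", "gene"))$r
    if (length(cr) >= 10L)
      ce <- decileEnrichment(cr, bundle$coexpr$r)
  }

  en <- sdel <- hap <- NULL
  if (energies) {
    eff_gwas <- effects[effects$snp_id %in% assignments$snp_id, ,
                        drop = FALSE]
    en <- energyTable(eff_gwas, bundle$transcripts, bundle$regions,
                      bundle$snps, bundle$mirnas)
    sdel <- snpEnergySummary(en)
    hap <- haplotypeScores(sdel, bundle$ld,
                           measure = if (config$ld_group_rule == "r2")
                             "r2" else "dprime",
                           threshold = config$dprime_min,
                           grouping = if (config$ld_group_rule == "clique")
                             "clique" else "component")
  }

  list(groups = groups, sites = sites, effects = effects,
       assignments = assignments, qq = qq, enrichment_or = eor,
       context = ctx, candidates = candidates, evaluation = evaluation,
       density = density, trilateral = tri, perturbing = perturbing,
       coexpr_enrichment = ce, energies = en, snp_deltas = sdel,
       haplotypes = hap)
}
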