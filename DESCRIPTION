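Package: mressnp
Title: Candidate Causal SNPs in MicroRNA Recognition Element Seed Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate causal single nucleotide polymorphisms
    (SNPs) located in microRNA recognition element seed sites (MRESSs) of
    mRNA 3'UTRs. Implements allele-aware seed-site prediction for the four
    canonical site types (7mer positions 1-7, 7mer positions 2-8, 8mer-1a
    and 8mer), create/loss calling for alternate alleles, a human-mouse
    conservation filter, inheritance of GWAS p-values through D'-based
    linkage-disequilibrium proxies, selection of candidates by Gene
    Ontology context shared with disease genes, evaluation against known
    deleterious SNPs, SNP-density comparisons across mRNA regions,
    microRNA-gene-disease trilateral interactions, co-expression decile
    enrichment, and nearest-neighbor RNA duplex thermodynamics (allele
    delta-delta-G and haplotype scores). A synthetic-data generator
    emulates every input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GenomeWideAssociation, SNP, GeneRegulation, Sequencing
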