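## One shared full-scale synthetic study (default generator conditions),
## computed lazily and reused by the acceptance checks that need a
## realistic cohort: purifying-selection recovery, duplex-energy
## direction and haplotype accounting.
.studyCache <- new.env(parent = emptyenv())

studyRunCached <- function(seed = 4242L) {
  key <- as.character(seed)
  if (is.null(.studyCache[[key]])) {
    b <- simulateBundle(simConfig(seed = seed))
    res <- runPipeline(b, conservation = FALSE, energies = TRUE)
    .studyCache[[key]] <- list(bundle = b, result = res)
  }
  .studyCache[[key]]
}
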