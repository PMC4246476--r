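#' SeedGroups: microRNAs grouped by identical seed sequence
#'
#' MicroRNAs sharing a 7-nt seed are scanned as one group. Two seed
#' definitions are kept side by side: positions 1-7 and positions 2-8 of the
#' mature sequence (5' end). For site typing each member also records its
#' "extra" base: position 8 for the 1-7 seed and position 1 for the 2-8
#' seed, because extending a 7-nt match by a complementary extra base
#' upgrades the site to an 8mer.
#'
#' @slot members data.frame with one row per (seed kind, member microRNA):
#'   columns `seed_kind` ("1-7" or "2-8"), `seed` (7-nt RNA string),
#'   `mirna_id`, `extra_base` (single RNA base).
#' @export
setClass("SeedGroups", representation(members = "data.frame"))

setValidity("SeedGroups", function(object) {
  m <- object@members
  need <- c("seed_kind", "seed", "mirna_id", "extra_base")
  if (!all(need %in% names(m)))
    return(paste("members must have columns:", paste(need, collapse = ", ")))
  if (nrow(m)) {
    if (!all(m$seed_kind %in% c("1-7", "2-8")))
      return("seed_kind must be '1-7' or '2-8'")
    if (any(nchar(m$seed) != 7L) || any(grepl("[^ACGU]", m$seed)))
      return("seeds must be 7-nt RNA strings")
    if (any(nchar(m$extra_base) != 1L) || any(grepl("[^ACGU]", m$extra_base)))
      return("extra_base must be a single RNA base")
    if (anyDuplicated(m[, c("seed_kind", "mirna_id")]))
      return("each microRNA may appear once per seed kind")
  }
  TRUE
})

#' @describeIn SeedGroups number of (seed kind, seed) groups
#' @param x,object a `SeedGroups` object
#' @export
setMethod("length", "SeedGroups", function(x) {
  nrow(unique(x@members[, c("seed_kind", "seed")]))
})

#' Access the member table of a SeedGroups object
#'
#' @param x a `SeedGroups` object.
#' @return data.frame with columns seed_kind, seed, mirna_id, extra_base.
#' @export
seedMembers <- function(x) {
  stopifnot(is(x, "SeedGroups"))
  x@members
}

setMethod("show", "SeedGroups", function(object) {
  m <- object@members
  for (kind in c("1-7", "2-8")) {
    sub <- m[m$seed_kind == kind, , drop = FALSE]
    cat(sprintf("SeedGroups kind %s: %d groups, %d microRNAs\n", kind,
                length(unique(sub$seed)), length(unique(sub$mirna_id))))
  }
  invisible(NULL)
})
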