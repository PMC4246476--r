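#' Convert a 1-based position to internal 0-based coordinates
#'
#' All file formats in this package use 1-based inclusive coordinates
#' (dbSNP/NCBI convention); internally every offset is 0-based half-open so
#' that interval arithmetic needs no off-by-one corrections.
#'
#' @param pos integer vector of 1-based positions (all >= 1).
#' @return integer vector of 0-based positions.
#' @seealso [toFileCoords()] for the inverse.
#' @export
#' @examples
#' toInternalCoords(1L)   # 0
#' toInternalCoords(100L) # 99
toInternalCoords <- function(pos) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("positions must be integers >= 1")
  pos - 1L
}

#' Convert an internal 0-based position to 1-based file coordinates
#'
#' @param pos integer vector of 0-based positions (all >= 0).
#' @return integer vector of 1-based positions.
#' @export
toFileCoords <- function(pos) {
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 0L))
    stop("positions must be integers >= 0")
  pos + 1L
}

## RNA alphabet helpers. Sequences are handled as plain uppercase RNA
## character strings internally; Biostrings objects are used at I/O and
## alignment boundaries.

.normalizeRna <- function(x) {
  x <- toupper(x)
  chartr("T", "U", x)
}

.checkRna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGU]", x)
  if (any(bad))
    stop(sprintf("non-RNA character in %s: %s", what,
                 paste(utils::head(x[bad], 3L), collapse = ", ")))
  invisible(x)
}

## complement of single RNA bases (vectorized over characters)
.compRna <- function(x) chartr("ACGU", "UGCA", x)

## complement of single DNA bases (forward-strand allele handling)
.compDna <- function(x) chartr("ACGT", "TGCA", x)

## reverse complement of RNA strings (vectorized)
.rcRna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(.compRna(s), "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

## TRUE where a and b are Watson-Crick partners (RNA, no wobble)
.isWcPair <- function(a, b) {
  (a == "A" & b == "U") | (a == "U" & b == "A") |
  (a == "C" & b == "G") | (a == "G" & b == "C")
}

.stopifnotCols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(df)
}
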