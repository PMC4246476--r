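#' Decile enrichment of candidate-affected pairs over co-expression
#' correlations
#'
#' Splits the candidate-affected microRNA-mRNA pairs into ten near-equal
#' groups by their Pearson correlation coefficients, bins the total pair
#' set into the same (low, high] intervals (outermost edges extended to
#' -1 and +1), and reports the base-10 log of the ratio of the two
#' proportions per interval. Positive values mean the candidate pairs are
#' enriched in that correlation range.
#'
#' @param candidateR numeric vector of correlations for candidate-affected
#'   pairs (length >= 10, values in \[-1, 1\]).
#' @param totalR numeric vector of correlations for the total pair set.
#' @return data.frame with ten rows: `low`, `high`, `n_candidate`,
#'   `n_total`, `log_ratio` (NA and `flagged = TRUE` for intervals holding
#'   no total pair).
#' @export
decileEnrichment <- function(candidateR, totalR) {
  candidateR <- candidateR[!is.na(candidateR)]
  totalR <- totalR[!is.na(totalR)]
  if (length(candidateR) < 10L)
    stop("need at least 10 candidate pairs to form deciles")
  if (any(abs(c(candidateR, totalR)) > 1))
    stop("correlations must lie in [-1, 1]")
  edges <- stats::quantile(candidateR, probs = seq(0, 1, by = 0.1),
                           names = FALSE, type = 7)
  edges[1L] <- -1; edges[11L] <- 1
  edges <- cummax(edges)  # guard against ties collapsing an interval
  bin <- function(x) {
    ## (low, high] membership; the lowest interval also includes x == -1
    i <- findInterval(x, edges, left.open = TRUE, rightmost.closed = FALSE)
    i[x == -1] <- 1L
    i[i < 1L] <- 1L; i[i > 10L] <- 10L
    tabulate(i, nbins = 10L)
  }
  nc <- bin(candidateR)
  nt <- bin(totalR)
  pc <- nc / length(candidateR)
  pt <- nt / length(totalR)
  lr <- ifelse(nt == 0L, NA_real_, log10(pc / pt))
  data.frame(low = edges[1:10], high = edges[2:11],
             n_candidate = nc, n_total = nt, log_ratio = lr,
             flagged = nt == 0L)
}
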