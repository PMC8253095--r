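# Factor-specific noise regions: a random set of coordinates matched to the
# source set in number and length and excluded from it, the signal null
# against which region classes are compared.

#' Length-matched random shuffle of genomic intervals
#'
#' For each source interval a placement is drawn uniformly over the genome
#' (chromosome chosen proportional to its length, unless `preserve_chrom`)
#' and accepted iff it lies within chromosome bounds and shares zero bases
#' with the exclusion set. Placed intervals may overlap one another —
#' deduplication would distort the length-matched null. Deterministic for a
#' fixed seed.
#'
#' @param source `GRanges` whose interval lengths are to be matched.
#' @param genome a `Genome` (only `sizes` is used).
#' @param exclusion `GRanges` that the output must not touch; defaults to
#'   `source` itself (the concatenated peak file).
#' @param seed integer seed (mandatory: the null must be reproducible).
#' @param max_attempts attempts per interval before a hard error.
#' @param preserve_chrom keep each interval on its source chromosome
#'   (useful on small synthetic genomes).
#' @return `GRanges` with metadata `seed` and `attempts_used`; same length
#'   multiset as `source`, zero overlap with `exclusion`.
#' @export
matched_shuffle <- function(source, genome, exclusion = source, seed,
                            max_attempts = 1000L, preserve_chrom = FALSE) {
  stopifnot(!missing(seed))
  sizes <- genome$sizes
  widths <- width(granges(source))
  if (!length(widths)) {
    out <- GRanges()
    metadata(out)$seed <- seed
    metadata(out)$attempts_used <- 0L
    return(out)
  }
  if (max(widths) > max(sizes))
    stop("a source interval is longer than the longest chromosome")
  src_chrom <- as.character(seqnames(source))
  excl <- sort(granges(exclusion))
  n <- length(widths)
  chrom_out <- character(n)
  start_out <- integer(n)  # 0-based
  pending <- seq_len(n)
  attempts <- 0L
  with_seed(seed, {
    while (length(pending)) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop(sprintf(
          "could not place interval %d (length %d) within %d attempts",
          pending[1], widths[pending[1]], max_attempts))
      w <- widths[pending]
      if (preserve_chrom) {
        ch <- src_chrom[pending]
      } else {
        ch <- sample(names(sizes), length(pending), replace = TRUE,
                     prob = sizes / sum(sizes))
      }
      # uniform 0-based start; may exceed the in-bounds range -> rejected
      s0 <- floor(runif(length(pending)) * sizes[ch])
      fits <- s0 + w <= sizes[ch]
      ok <- rep(FALSE, length(pending))
      if (any(fits)) {
        cand <- GRanges(ch[fits], IRanges(start = s0[fits] + 1L,
                                          width = w[fits]))
        clean <- countOverlaps(cand, excl, minoverlap = 1L) == 0L
        ok[fits] <- clean
      }
      placed <- pending[ok]
      chrom_out[placed] <- ch[ok]
      start_out[placed] <- s0[ok]
      pending <- pending[!ok]
    }
  })
  out <- gintervals(chrom_out, start_out, start_out + widths)
  metadata(out)$seed <- seed
  metadata(out)$attempts_used <- attempts
  out
}
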