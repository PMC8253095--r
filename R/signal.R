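# Fragment counting in regions, CPM normalisation, binned signal matrices
# centred on region midpoints, and rank-sum comparisons between region classes.

#' Bundle aligned fragments with their library size
#'
#' Single-end reads are treated as fragments of their aligned length, without
#' extension. `library_size` defaults to the number of fragments present but
#' may exceed it when clipped records were dropped upstream.
#'
#' @param fragments `GRanges` of aligned fragment intervals.
#' @param library_size total mapped fragments for CPM scaling.
#' @param sample_id,factor optional labels.
#' @return Object of class `FragmentSet`.
#' @export
fragment_set <- function(fragments, library_size = length(fragments),
                         sample_id = NA_character_, factor = NA_character_) {
  stopifnot(library_size >= length(fragments))
  structure(list(fragments = granges(fragments),
                 library_size = as.numeric(library_size),
                 sample_id = sample_id, factor = factor),
            class = "FragmentSet")
}

#' Count fragments overlapping each region
#'
#' Any-overlap counting (>= 1 bp): a fragment overlapping two regions
#' increments both. Half-open semantics mean an abutting fragment does not
#' count.
#'
#' @param frags a `FragmentSet` (or bare `GRanges`).
#' @param regions `GRanges`, merged.
#' @return Integer vector, one count per region.
#' @export
count_fragments_in_regions <- function(frags, regions) {
  gr <- if (inherits(frags, "FragmentSet")) frags$fragments else frags
  countOverlaps(regions, gr, minoverlap = 1L)
}

#' Counts-per-million normalisation
#'
#' `CPM(r, s) = counts(r, s) * 1e6 / library_size(s)`.
#'
#' @param counts numeric vector or regions x samples matrix of raw counts.
#' @param library_sizes per-sample library sizes (recycled for a vector).
#' @return CPM values with the shape of `counts`.
#' @export
cpm_normalize <- function(counts, library_sizes) {
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (is.matrix(counts)) {
    stopifnot(length(library_sizes) == ncol(counts))
    sweep(counts, 2L, library_sizes, "/") * 1e6
  } else {
    counts * 1e6 / library_sizes
  }
}

#' Binned CPM signal matrix centred on region midpoints
#'
#' Rows are regions, columns are `2 * flank / bin_size` bins of `bin_size` bp
#' spanning `[midpoint - flank, midpoint + flank)`; the midpoint is
#' `floor((start + end) / 2)`. Each value is the mean per-bp fragment coverage
#' in the bin scaled to CPM. Bins that fall outside the chromosome are `NA`.
#' Rows are returned in region order; `attr(, "display_order")` gives the
#' descending-row-sum ordering used for heatmap export.
#'
#' @param frags a `FragmentSet` (or bare `GRanges`, in which case
#'   `library_size` must be given).
#' @param regions `GRanges` whose midpoints anchor the rows.
#' @param genome a `Genome` (for chromosome bounds).
#' @param flank half-window in bp (2000 for site heatmaps, 5000 for broad
#'   context views); must be divisible by `bin_size`.
#' @param bin_size bin width in bp (default 25).
#' @param library_size override for the CPM denominator.
#' @return Numeric matrix regions x bins with attributes `flank`, `bin_size`,
#'   `display_order`.
#' @export
signal_matrix <- function(frags, regions, genome, flank = 2000L,
                          bin_size = 25L, library_size = NULL) {
  if (inherits(frags, "FragmentSet")) {
    if (is.null(library_size)) library_size <- frags$library_size
    frags <- frags$fragments
  }
  if (is.null(library_size)) library_size <- length(frags)
  if (flank %% bin_size != 0) stop("flank must be divisible by bin_size")
  nbins <- as.integer(2L * flank / bin_size)
  n <- length(regions)
  out <- matrix(NA_real_, nrow = n, ncol = nbins)
  if (!n) {
    attr(out, "flank") <- flank; attr(out, "bin_size") <- bin_size
    attr(out, "display_order") <- integer(0)
    return(out)
  }
  cov <- GenomicRanges::coverage(granges(frags))
  mid0 <- floor((bed_start(regions) + bed_end(regions)) / 2)  # 0-based
  win_s0 <- mid0 - flank                                      # 0-based window start
  chrom <- as.character(seqnames(regions))
  binidx <- rep(seq_len(nbins), each = bin_size)
  for (i in seq_len(n)) {
    ch <- chrom[i]
    chlen <- genome$sizes[[ch]]
    lo <- win_s0[i]; hi <- win_s0[i] + 2L * flank   # 0-based half-open window
    vlo <- max(lo, 0L); vhi <- min(hi, chlen)
    if (vlo >= vhi) next
    rle <- if (ch %in% names(cov)) cov[[ch]] else S4Vectors::Rle(0L, chlen)
    if (length(rle) < vhi) rle <- c(rle, S4Vectors::Rle(0L, vhi - length(rle)))
    vals <- rep(NA_real_, 2L * flank)
    vals[(vlo - lo + 1L):(vhi - lo)] <-
      as.numeric(S4Vectors::window(rle, start = vlo + 1L, end = vhi))
    bin_means <- tapply(vals, binidx, function(v)
      if (all(is.na(v))) NA_real_ else mean(v))
    out[i, ] <- as.numeric(bin_means)
  }
  out <- out * 1e6 / library_size
  attr(out, "flank") <- flank
  attr(out, "bin_size") <- bin_size
  attr(out, "display_order") <- order(rowSums(out, na.rm = TRUE),
                                      decreasing = TRUE)
  out
}

#' Column-mean profile of a signal matrix
#' @param m matrix from [signal_matrix()].
#' @return Numeric vector of per-bin means (NA bins excluded).
#' @export
signal_profile <- function(m) colMeans(m, na.rm = TRUE)

#' Two-sided Wilcoxon/Mann-Whitney rank-sum test
#'
#' Exact by full enumeration of group assignments when `n_a * n_b <= 64`
#' (correct under ties); otherwise the normal approximation with tie and
#' continuity corrections. When every value is tied across both samples the
#' test is degenerate and `p = 1`.
#'
#' @param a,b numeric samples (e.g. log fragment counts of two region classes).
#' @return List with `statistic` (Mann-Whitney U of `a`), `p_value`, `n_a`,
#'   `n_b`, `method` (`"exact"` or `"normal-approximation"`), `degenerate`.
#' @export
rank_sum_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 1, nb >= 1)
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = na * nb / 2, p_value = 1, n_a = na, n_b = nb,
                method = if (na * nb <= 64) "exact" else "normal-approximation",
                degenerate = TRUE))
  }
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  EU <- na * nb / 2
  if (na * nb <= 64) {
    idx <- combn(na + nb, na)
    rs <- colSums(matrix(r[idx], nrow = na))
    Us <- rs - na * (na + 1) / 2
    p <- mean(abs(Us - EU) >= abs(U_obs - EU) - 1e-9)
    method <- "exact"
  } else {
    N <- na + nb
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (N * (N - 1))
    sigma <- sqrt(na * nb / 12 * ((N + 1) - tie_term))
    cc <- if (abs(U_obs - EU) > 0.5) 0.5 else 0
    z <- (U_obs - EU - sign(U_obs - EU) * cc) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(statistic = U_obs, p_value = p, n_a = na, n_b = nb,
       method = method, degenerate = FALSE)
}

#' Log-transformed fragment counts for a region class
#'
#' Natural log of `count + 1`, the transform used for the shared / specific /
#' noise signal comparisons.
#'
#' @param frags a `FragmentSet` or `GRanges`.
#' @param regions `GRanges`.
#' @return Numeric vector `log(count + 1)` per region.
#' @export
log_region_counts <- function(frags, regions) {
  log(count_fragments_in_regions(frags, regions) + 1)
}

#' Plot mean signal profiles of region classes
#'
#' Column-mean CPM profiles of one or more signal matrices over a common
#' bin axis, e.g. shared sites against matched noise.
#'
#' @param matrices named list of matrices from [signal_matrix()] sharing
#'   `flank`/`bin_size`.
#' @param path output SVG path (optional; default draws to the active
#'   device).
#' @return Invisibly, the matrix of profiles (bins x classes).
#' @export
plot_signal_profile <- function(matrices, path = NULL) {
  stopifnot(length(matrices) >= 1, !is.null(names(matrices)))
  flank <- attr(matrices[[1]], "flank")
  bin <- attr(matrices[[1]], "bin_size")
  prof <- vapply(matrices, signal_profile,
                 numeric(ncol(matrices[[1]])))
  x <- seq(-flank + bin / 2, flank - bin / 2, by = bin)
  if (!is.null(path)) {
    grDevices::svg(path, width = 6, height = 4.5)
    on.exit(grDevices::dev.off())
  }
  graphics::matplot(x, prof, type = "l", lty = 1, lwd = 2,
                    col = seq_len(ncol(prof)),
                    xlab = "distance from site centre (bp)",
                    ylab = "mean CPM coverage")
  graphics::legend("topright", legend = colnames(prof), lty = 1, lwd = 2,
                   col = seq_len(ncol(prof)), bty = "n")
  invisible(prof)
}
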