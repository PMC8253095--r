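# Dual-caller consensus peaks, peak-count QC, and shared/specific membership.

#' Intersect peaks from two callers
#'
#' Keeps the caller-1 peaks that overlap (>= 1 bp) at least one caller-2 peak.
#' Caller-1 coordinates are retained, preserving peak width information,
#' rather than clipping to the geometric intersection segment.
#'
#' @param caller1,caller2 `GRanges` of peaks from the same sample/factor.
#' @return Sorted `GRanges` of consensus peaks (caller-1 coordinates).
#' @export
intersect_caller_peaks <- function(caller1, caller2) {
  keep <- countOverlaps(caller1, caller2, minoverlap = 1L) > 0L
  sort(granges(caller1)[keep])
}

#' Peak-count quality control with a Tukey lower fence
#'
#' A sample is excluded when its peak count falls below
#' `Q1 - 1.5 * IQR` of the per-factor peak-count distribution (quantiles by
#' linear interpolation, `type = 7`) or below the absolute floor `min_peaks`
#' (default 10000). With a single sample, only the absolute floor applies and
#' the report carries a warning flag.
#'
#' @param counts named integer vector of peak counts, one per sample, for a
#'   single factor.
#' @param min_peaks absolute minimum peak count (default 10000).
#' @return `data.frame` with columns `sample`, `peak_count`, `excluded`,
#'   `exclusion_reason`; attributes `fence` (the lower fence) and
#'   `single_sample_warning`.
#' @export
qc_filter <- function(counts, min_peaks = 10000L) {
  stopifnot(length(counts) >= 1)
  if (is.null(names(counts))) names(counts) <- paste0("sample", seq_along(counts))
  single <- length(counts) < 2
  fence <- NA_real_
  if (!single) {
    q1 <- unname(quantile(counts, 0.25, type = 7))
    q3 <- unname(quantile(counts, 0.75, type = 7))
    fence <- q1 - 1.5 * (q3 - q1)
  }
  below_fence <- if (single) rep(FALSE, length(counts)) else counts < fence
  below_floor <- counts < min_peaks
  reason <- character(length(counts))
  reason[below_floor] <- sprintf("peak count %d < min_peaks %d",
                                 counts[below_floor], as.integer(min_peaks))
  reason[below_fence & !below_floor] <-
    sprintf("peak count %d < Q1 - 1.5*IQR (%.1f)",
            counts[below_fence & !below_floor], fence)
  reason[below_fence & below_floor] <-
    sprintf("peak count %d < min_peaks %d and < Q1 - 1.5*IQR (%.1f)",
            counts[below_fence & below_floor], as.integer(min_peaks), fence)
  out <- data.frame(sample = names(counts),
                    peak_count = as.integer(counts),
                    excluded = below_fence | below_floor,
                    exclusion_reason = reason,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fence") <- fence
  attr(out, "single_sample_warning") <- single
  out
}

#' Cross-sample membership decomposition of consensus regions
#'
#' Consensus regions are the gap-0 merge of the concatenation of all samples'
#' peaks; occupancy is any-overlap (>= 1 bp). Each region is classed
#' `shared_all` (occupied by every sample), `specific:<sample>` (exactly one),
#' or `partial` (more than one but not all).
#'
#' @param peak_sets named list of `GRanges`, one per sample, same factor.
#' @return List with `regions` (merged `GRanges`), `occupancy` (logical
#'   regions x samples matrix), `class` (character per region),
#'   `class_counts` (named integer over occupancy patterns, UpSet-style),
#'   and `shared_fraction`. The shared fraction is
#'   `n_shared / (n_shared + mean_s n_specific(s))`: the Venn centre against
#'   the average single-sample exclusive count. Partial regions are reported
#'   but excluded from this summary, as they are from the downstream
#'   shared-vs-specific contrasts.
#' @export
build_membership <- function(peak_sets) {
  stopifnot(is.list(peak_sets), length(peak_sets) >= 1)
  if (is.null(names(peak_sets)))
    names(peak_sets) <- paste0("sample", seq_along(peak_sets))
  regions <- merge_intervals(do.call(c, lapply(unname(peak_sets), granges)), gap = 0L)
  occ <- vapply(peak_sets,
                function(p) countOverlaps(regions, p, minoverlap = 1L) > 0L,
                logical(length(regions)))
  occ <- matrix(occ, nrow = length(regions),
                dimnames = list(NULL, names(peak_sets)))
  n_occ <- rowSums(occ)
  stopifnot(all(n_occ >= 1))
  cls <- rep("partial", length(regions))
  cls[n_occ == ncol(occ)] <- "shared_all"
  one <- n_occ == 1L
  cls[one] <- paste0("specific:", colnames(occ)[max.col(occ[one, , drop = FALSE])])
  if (ncol(occ) == 1L) cls <- paste0("specific:", colnames(occ))
  pattern <- apply(occ, 1L, function(r) paste(colnames(occ)[r], collapse = "&"))
  class_counts <- table(pattern)
  class_counts <- setNames(as.integer(class_counts), names(class_counts))
  n_shared <- sum(cls == "shared_all")
  mean_specific <- mean(vapply(colnames(occ), function(s)
    sum(cls == paste0("specific:", s)), numeric(1)))
  list(regions = regions, occupancy = occ, class = cls,
       class_counts = class_counts,
       shared_fraction = n_shared / (n_shared + mean_specific))
}

#' Extract one membership class as a GRanges
#'
#' @param membership result of [build_membership()].
#' @param class `"shared_all"`, `"partial"`, or `"specific:<sample>"`.
#' @return `GRanges` of the regions in that class.
#' @export
membership_regions <- function(membership, class) {
  membership$regions[membership$class == class]
}

#' Fraction of peaks in one set overlapping another
#'
#' Asymmetric by construction: the denominator is `|a|`. The pipeline reports
#' both directions.
#'
#' @param a,b `GRanges` of peaks for the same factor.
#' @return Fraction in `[0, 1]`; `NA` when `a` is empty.
#' @export
pairwise_overlap_fraction <- function(a, b) {
  if (!length(a)) return(NA_real_)
  if (!length(b)) return(0)
  mean(countOverlaps(a, b, minoverlap = 1L) > 0L)
}
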