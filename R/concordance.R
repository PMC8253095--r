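# Cross-sample Pearson correlation matrices (reads-in-peaks or expression)
# and unsupervised hierarchical clustering with complete linkage.

#' Pairwise Pearson correlation of labelled columns
#'
#' @param m numeric matrix, observations x labelled columns (>= 2 columns).
#' @return Symmetric correlation matrix; correlations involving a
#'   zero-variance column are `NA` (flagged in `attr(, "zero_variance")`),
#'   never reported as 0.
#' @export
correlation_matrix <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) >= 2)
  zv <- apply(m, 2L, function(x) var(x, na.rm = TRUE) == 0 || all(is.na(x)))
  cm <- suppressWarnings(cor(m, use = "pairwise.complete.obs"))
  cm[zv, ] <- NA_real_
  cm[, zv] <- NA_real_
  diag(cm)[!zv] <- 1
  attr(cm, "zero_variance") <- colnames(m)[zv]
  cm
}

#' Complete-linkage clustering of a correlation matrix
#'
#' Agglomerative clustering on the distance `d = 1 - r` with complete
#' linkage. Labels are ordered lexicographically before clustering so tied
#' merges resolve deterministically regardless of input column order.
#'
#' @param cmat correlation matrix from [correlation_matrix()]; clustered
#'   labels must have no missing entries.
#' @param distance `"one_minus_r"` (default) or `"euclidean"` (Euclidean
#'   distance between correlation profiles).
#' @return `hclust` object (merge heights non-decreasing under complete
#'   linkage); Newick export via [dendrogram_newick()].
#' @export
hierarchical_cluster <- function(cmat, distance = c("one_minus_r", "euclidean")) {
  distance <- match.arg(distance)
  if (ncol(cmat) < 2) stop("need >= 2 labels to cluster")
  if (anyNA(cmat)) stop("missing correlations among clustered labels")
  o <- order(colnames(cmat))
  cmat <- cmat[o, o]
  d <- if (distance == "one_minus_r") as.dist(1 - cmat)
       else dist(cmat)
  hclust(d, method = "complete")
}

#' Newick string of a dendrogram
#' @param hc an `hclust` object.
#' @return Single Newick string with branch lengths.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Merge table of a dendrogram
#' @param hc an `hclust` object.
#' @return `data.frame` with columns `left`, `right` (negative = leaf index),
#'   `height`.
#' @export
dendrogram_merges <- function(hc) {
  data.frame(left = hc$merge[, 1], right = hc$merge[, 2],
             height = hc$height)
}

#' Leaf groups cut at k clusters
#' @param hc an `hclust` object.
#' @param k number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_groups <- function(hc, k) stats::cutree(hc, k = k)
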