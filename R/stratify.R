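# k-means stratification of a binned signal matrix; the top-ranked clusters
# (by mean signal in the central window) form the "active" subset, e.g.
# H3K27ac-positive sample-specific binding sites.

# k-means++ seeding: first centre uniform, subsequent centres with probability
# proportional to squared distance from the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j] <- sample.int(n, 1L, prob = prob)
    nd <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

#' Stratify regions by k-means on their signal matrix
#'
#' Lloyd's k-means on row vectors (Euclidean), initialised k-means++ style
#' from `seed`, with `restarts` restarts keeping the solution with the lowest
#' within-cluster sum of squares. Clusters are ranked by their mean signal in
#' the central window (+/- `central_bins` bins around the matrix centre) and
#' the union of the top `n_top` clusters is flagged as selected. Missing bins
#' are imputed to 0 before clustering. Deterministic for a fixed seed.
#'
#' @param m numeric matrix from [signal_matrix()] (regions x bins).
#' @param k number of clusters (default 4; always logged — the choice is a
#'   configuration value, not inferred).
#' @param seed RNG seed (default 1729).
#' @param n_top number of top-ranked clusters selected (default 2).
#' @param central_bins half-width of the central ranking window in bins.
#' @param restarts number of k-means++ restarts (default 10).
#' @return List with `cluster` (id per region), `ranking` (cluster ids, best
#'   first), `selected` (logical per region), `cluster_central_mean`, `wss`,
#'   `k`, `seed`, `empty_clusters`.
#' @export
kmeans_stratify <- function(m, k = 4L, seed = 1729L, n_top = 2L,
                            central_bins = 10L, restarts = 10L) {
  stopifnot(k >= n_top, n_top >= 1)
  if (nrow(m) < k) stop("fewer rows than clusters requested")
  x <- as.matrix(m)
  x[is.na(x)] <- 0
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      centers <- kmeanspp_centers(x, k)
      fit <- suppressWarnings(
        kmeans(x, centers = centers, iter.max = 100L, algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  nb <- ncol(x)
  ctr <- max(1L, floor(nb / 2) - central_bins + 1L):min(nb, floor(nb / 2) + central_bins)
  central <- rowMeans(x[, ctr, drop = FALSE])
  cl_mean <- vapply(seq_len(k), function(j) {
    v <- central[best$cluster == j]
    if (length(v)) mean(v) else -Inf
  }, numeric(1))
  ranking <- order(cl_mean, decreasing = TRUE)
  top <- ranking[seq_len(n_top)]
  list(cluster = best$cluster,
       ranking = ranking,
       selected = best$cluster %in% top,
       cluster_central_mean = cl_mean,
       wss = best$tot.withinss,
       k = k, seed = seed,
       empty_clusters = setdiff(seq_len(k), unique(best$cluster)))
}

#' Jaccard index of two index/logical sets
#' @param a,b logical vectors of equal length, or integer index vectors.
#' @return `|a & b| / |a | b|`.
#' @export
jaccard_index <- function(a, b) {
  if (is.logical(a) && is.logical(b)) {
    u <- sum(a | b)
    if (u == 0) return(NA_real_)
    return(sum(a & b) / u)
  }
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}
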