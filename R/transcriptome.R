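# Expression normalisation (median-of-ratios size factors), low-expression
# filtering, log transform, and a simplified two-group negative-binomial Wald
# test with BH correction and effect-size thresholds.

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, each sample's factor is the
#' median over those genes of `count(g, s) / geometric_mean_over_samples(g)`.
#'
#' @param counts genes x samples matrix of raw counts (non-negative integers).
#' @param pseudo_reference when no gene is nonzero in all samples, fall back
#'   to a pseudo-reference built from genes with nonzero geometric mean over
#'   the samples where they are expressed (default `FALSE`: error instead).
#' @return Named numeric vector of size factors (> 0).
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(counts >= 0))
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero)) {
    if (!pseudo_reference)
      stop("no gene has nonzero counts in all samples; ",
           "re-run with pseudo_reference = TRUE")
    logmeans <- rowMeans(log(counts + 0.5))
    use <- rep(TRUE, nrow(counts))
  } else {
    logmeans <- rowMeans(log(counts))
    use <- all_nonzero
  }
  sf <- apply(counts, 2L, function(col) {
    ratios <- log(col[use] + if (any(all_nonzero)) 0 else 0.5) - logmeans[use]
    exp(median(ratios))
  })
  stopifnot(all(sf > 0))
  sf
}

#' Library-size normalised counts
#' @param counts genes x samples matrix.
#' @param sf size factors (default: computed by [size_factors()]).
#' @return Matrix of `counts / sf` per column.
#' @export
normalize_counts <- function(counts, sf = size_factors(counts)) {
  sweep(as.matrix(counts), 2L, sf, "/")
}

#' Remove unexpressed genes and log-transform
#'
#' A gene is removed iff its normalised count is below `floor` in every
#' sample (genes that are never expressed); retained values are transformed
#' `log2(x + 1)`. The stricter any-sample reading of the filter is available
#' via `mode = "any"`.
#'
#' @param normalized genes x samples matrix of normalised counts.
#' @param floor expression floor (default 4).
#' @param mode `"all"` (drop when below floor in all samples; default) or
#'   `"any"` (drop when below floor in any sample).
#' @return `log2(x + 1)` matrix of retained genes.
#' @export
filter_and_log <- function(normalized, floor = 4, mode = c("all", "any")) {
  mode <- match.arg(mode)
  m <- as.matrix(normalized)
  keep <- if (mode == "all") apply(m, 1L, max) >= floor
          else apply(m, 1L, min) >= floor
  log2(m[keep, , drop = FALSE] + 1)
}

# mean-dispersion trend alpha(mu) = a0 + a1/mu fitted to positive
# method-of-moments estimates (least squares on 1/mu), clamped >= 0
fit_dispersion_trend <- function(mu, alpha_raw) {
  ok <- is.finite(alpha_raw) & alpha_raw > 0 & mu > 0
  if (sum(ok) < 10) {
    a <- c(max(mean(alpha_raw[is.finite(alpha_raw)], na.rm = TRUE), 1e-4), 0)
  } else {
    fit <- lm(alpha_raw[ok] ~ I(1 / mu[ok]))
    a <- pmax(coef(fit), 0)
    if (!is.finite(a[1]) || a[1] <= 0) a[1] <- 1e-4
  }
  function(m) pmax(a[1] + a[2] / pmax(m, 1e-8), 1e-8)
}

#' Two-group negative-binomial Wald differential expression
#'
#' A deliberately simple NB Wald test for a 2-vs-2 (or larger) two-group
#' design: per gene, normalised group means enter
#' `log2FC = log2((mu_b + 0.5) / (mu_a + 0.5))`; the gene-wise dispersion is
#' estimated by method of moments from the pooled within-group variance of
#' normalised counts and shrunk 50/50 toward a fitted mean-dispersion trend
#' `a0 + a1/mu`; the Wald standard error comes from the NB variance
#' `mu + alpha mu^2` by the delta method. P-values are two-sided normal, BH
#' adjusted across tested genes. A gene passes when `fdr <= fdr_max` and
#' `|log2FC| >= lfc_min`.
#'
#' @param counts genes x samples raw count matrix with column names.
#' @param group_a,group_b character vectors of sample (column) names;
#'   at least 2 samples per group.
#' @param sf size factors (default [size_factors()] of `counts`).
#' @param fdr_max FDR threshold for the pass flag (default 0.05).
#' @param lfc_min absolute log2 fold-change threshold (default 2).
#' @return `data.frame` with `gene_id`, `base_mean`, `log2fc`, `se`,
#'   `p_value`, `fdr`, `pass`; genes all-zero in both groups are excluded.
#' @export
differential_expression <- function(counts, group_a, group_b,
                                    sf = NULL, fdr_max = 0.05, lfc_min = 2) {
  counts <- as.matrix(counts)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2,
            all(c(group_a, group_b) %in% colnames(counts)))
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  a <- norm[, group_a, drop = FALSE]
  b <- norm[, group_b, drop = FALSE]
  tested <- rowSums(a) + rowSums(b) > 0
  a <- a[tested, , drop = FALSE]; b <- b[tested, , drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  mu_a <- rowMeans(a); mu_b <- rowMeans(b)
  mu <- (na * mu_a + nb * mu_b) / (na + nb)
  v_pool <- (apply(a, 1L, var) * (na - 1) + apply(b, 1L, var) * (nb - 1)) /
    (na + nb - 2)
  alpha_raw <- (v_pool - mu) / mu^2
  trend <- fit_dispersion_trend(mu, alpha_raw)
  alpha <- 0.5 * pmax(alpha_raw, 0) + 0.5 * trend(mu)
  log2fc <- log2((mu_b + 0.5) / (mu_a + 0.5))
  var_log2 <- function(m, n) (m + alpha * m^2) / n / ((m + 0.5)^2 * log(2)^2)
  se <- sqrt(var_log2(mu_a, na) + var_log2(mu_b, nb))
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(gene_id = rownames(counts)[tested],
                    base_mean = mu, log2fc = log2fc, se = se,
                    p_value = p, fdr = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$pass <- out$fdr <= fdr_max & abs(out$log2fc) >= lfc_min
  rownames(out) <- NULL
  out
}

#' Read a gene-by-sample count table from TSV
#' @param path TSV with a gene-id first column and one column per sample.
#' @return Integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                   check.names = FALSE)
  as.matrix(df)
}
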