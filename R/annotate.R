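# Genomic-context annotation, TSS-proximity peak-to-gene linkage, and
# hypergeometric gene-set over-representation with BH correction.

#' Genomic-context distribution of regions
#'
#' Each region is classified by its midpoint with precedence
#' promoter > exon > intron > downstream > distal intergenic.
#' The promoter is `[TSS - promoter_flank, TSS + promoter_flank)`;
#' downstream extends `promoter_flank` bp past the 3' gene end. When the
#' annotation carries no exon intervals, midpoints inside a gene body
#' (outside the promoter) are classed intron.
#'
#' @param regions non-empty `GRanges`.
#' @param ann gene annotation `data.frame` from [read_gene_annotation()].
#' @param promoter_flank promoter half-width in bp (default 1000).
#' @param exons optional `GRanges` of exon intervals.
#' @return Named numeric vector of percentages over
#'   `c("promoter", "exon", "intron", "downstream", "distal_intergenic")`,
#'   summing to 100.
#' @export
genomic_context <- function(regions, ann, promoter_flank = 1000L,
                            exons = NULL) {
  if (!length(regions)) stop("empty region set")
  mid0 <- floor((bed_start(regions) + bed_end(regions)) / 2)
  mid <- GRanges(seqnames(regions), IRanges(start = mid0 + 1L, width = 1L))
  cats <- c("promoter", "exon", "intron", "downstream", "distal_intergenic")
  cls <- rep("distal_intergenic", length(regions))
  if (nrow(ann)) {
    prom0 <- pmax(ann$tss - promoter_flank, 0L)
    prom <- GRanges(ann$chrom, IRanges(start = prom0 + 1L,
                                       end = ann$tss + promoter_flank))
    body <- GRanges(ann$chrom, IRanges(start = ann$start + 1L, end = ann$end))
    dn_s0 <- ifelse(ann$strand == "+", ann$end, pmax(ann$start - promoter_flank, 0L))
    dn_e0 <- ifelse(ann$strand == "+", ann$end + promoter_flank, ann$start)
    keep_dn <- dn_e0 > dn_s0
    down <- GRanges(ann$chrom[keep_dn],
                    IRanges(start = dn_s0[keep_dn] + 1L, end = dn_e0[keep_dn]))
    in_prom <- countOverlaps(mid, prom) > 0L
    in_exon <- if (!is.null(exons) && length(exons))
      countOverlaps(mid, exons) > 0L else rep(FALSE, length(mid))
    in_body <- countOverlaps(mid, body) > 0L
    in_down <- countOverlaps(mid, down) > 0L
    cls[in_down] <- "downstream"
    cls[in_body] <- "intron"
    cls[in_exon & in_body] <- "exon"
    cls[in_prom] <- "promoter"
  }
  pct <- 100 * vapply(cats, function(ct) mean(cls == ct), numeric(1))
  stopifnot(abs(sum(pct) - 100) < 0.01)
  pct
}

#' Link regions to genes by TSS proximity
#'
#' Each region is assigned the gene whose TSS is nearest its midpoint,
#' provided the distance is at most `window` bp (20 kb by default). Regions
#' with no TSS within the window stay unassigned; equidistant TSS ties keep
#' all tied genes. The gene list is deduplicated.
#'
#' @param regions `GRanges`.
#' @param ann gene annotation `data.frame` from [read_gene_annotation()].
#' @param window maximum midpoint-to-TSS distance in bp (default 20000).
#' @return List with `genes` (unique gene ids) and `table`
#'   (`data.frame` region_index, gene_id, distance).
#' @export
link_regions_to_genes <- function(regions, ann, window = 20000L) {
  stopifnot(window > 0)
  mid0 <- floor((bed_start(regions) + bed_end(regions)) / 2)
  chrom <- as.character(seqnames(regions))
  rows <- vector("list", length(regions))
  ann_by_chrom <- split(ann, ann$chrom)
  for (i in seq_along(regions)) {
    sub <- ann_by_chrom[[chrom[i]]]
    if (is.null(sub) || !nrow(sub)) next
    d <- abs(sub$tss - mid0[i])
    dmin <- min(d)
    if (dmin > window) next
    hit <- which(d == dmin)
    rows[[i]] <- data.frame(region_index = i, gene_id = sub$gene_id[hit],
                            distance = dmin, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(region_index = integer(0), gene_id = character(0),
                      distance = numeric(0))
  list(genes = unique(tab$gene_id), table = tab)
}

#' Read gene sets from a GMT file
#' @param path GMT path (set name, description, then member genes, tab-sep).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) stop("malformed GMT line ", bad[1], ": fewer than 3 fields")
  setNames(lapply(fields, function(f) unique(f[-(1:2)])),
           vapply(fields, `[[`, "", 1L))
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric p for each set:
#' `p = sum_{i >= k} C(K, i) C(N-K, n-i) / C(N, n)` with `N` the universe
#' size, `K` the set size (within the universe), `n` the query size and `k`
#' the overlap. Benjamini-Hochberg FDR across all tested sets; results sorted
#' by FDR then p.
#'
#' @param query character vector of gene ids (genes outside the universe are
#'   dropped with a warning).
#' @param sets named list of gene-id vectors (intersected with the universe).
#' @param universe character vector of all eligible gene ids (default in the
#'   pipeline: every annotated gene; logged in every report).
#' @param top_n number of top sets reported (default 12).
#' @return `data.frame` with columns `set_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, `fdr`, `genes`
#'   (comma-separated overlapping ids); at most `top_n` rows;
#'   full table in `attr(, "all")`.
#' @export
hypergeometric_enrichment <- function(query, sets, universe, top_n = 12L) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  dropped <- setdiff(query, universe)
  if (length(dropped))
    warning(length(dropped), " query gene(s) outside the universe dropped")
  query <- unique(intersect(query, universe))
  N <- length(universe); n <- length(query)
  res <- lapply(names(sets), function(nm) {
    K_genes <- intersect(sets[[nm]], universe)
    ov <- intersect(query, K_genes)
    k <- length(ov); K <- length(K_genes)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p_value = p,
               genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$fdr, out$p_value, out$set_name), ]
  rownames(out) <- NULL
  top <- head(out, top_n)
  attr(top, "all") <- out
  top
}
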