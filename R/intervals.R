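#' @import methods
#' @importFrom stats median quantile var sd cor complete.cases p.adjust phyper
#'   pnorm rnorm runif rpois rnbinom rlnorm setNames kmeans as.dist hclust
#'   dist na.omit lm coef
#' @importFrom utils read.table write.table head combn
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- queryHits subjectHits
#' @importFrom IRanges IRanges ranges width reduce findOverlaps
#' @importFrom GenomicRanges GRanges seqnames start end strand granges
#'   countOverlaps
#' @importFrom GenomeInfoDb seqlevels seqlevelsInUse
#' @importFrom BiocGenerics sort
NULL

# Genomic intervals follow the BED convention throughout: 0-based, half-open
# [start, end). A GRanges (1-based, closed) stores the same interval as
# [start+1, end]; the readers/writers below do that shift so that width and
# overlap semantics are preserved exactly (abutting BED intervals never overlap).

#' Build a GRanges from BED-convention coordinates
#'
#' Core constructor used throughout the package: takes 0-based half-open
#' coordinates and returns the equivalent `GRanges`.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param name optional name column.
#' @param score optional numeric score column.
#' @return A `GRanges` with optional `name`/`score` metadata columns.
#' @export
gintervals <- function(chrom, start, end, name = NULL, score = NULL) {
  if (length(start) && any(start < 0))
    stop("interval start must be >= 0")
  if (length(start) && any(start >= end))
    stop("interval start must be < end")
  gr <- GRanges(chrom, IRanges(start = as.integer(start) + 1L,
                               end = as.integer(end)))
  if (!is.null(name)) mcols(gr)$name <- name
  if (!is.null(score)) mcols(gr)$score <- score
  gr
}

#' 0-based start coordinates of a GRanges
#' @param gr a `GRanges`.
#' @return Integer vector of BED-convention starts.
#' @export
bed_start <- function(gr) start(gr) - 1L

#' Exclusive end coordinates of a GRanges
#' @param gr a `GRanges`.
#' @return Integer vector of BED-convention (exclusive) ends.
#' @export
bed_end <- function(gr) end(gr)

#' Read a BED file into a GRanges
#'
#' Parses BED3/BED6 (first six columns honoured; extra columns ignored).
#' Comment (`#`), `track` and `browser` lines are skipped. Record order is
#' preserved; whether the file was coordinate-sorted is recorded in
#' `metadata(x)$sorted`.
#'
#' @param path path to a BED file.
#' @return `GRanges`; `metadata()$sorted` flags coordinate-sortedness.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    gr <- GRanges()
    metadata(gr)$sorted <- TRUE
    return(gr)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("malformed BED line ", idx[which(nf < 3)[1]], ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": non-integer coordinates")
  bad <- which(s >= e | s < 0)
  if (length(bad))
    stop("malformed BED line ", idx[bad[1]], ": start >= end or negative")
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  score <- suppressWarnings(
    as.numeric(ifelse(nf >= 5, vapply(fields, function(f) f[min(5L, length(f))], ""), NA)))
  gr <- gintervals(chrom, s, e)
  if (any(nf >= 4)) mcols(gr)$name <- name
  if (any(nf >= 5)) mcols(gr)$score <- score
  o <- order(as.character(seqnames(gr)), start(gr), end(gr))
  metadata(gr)$sorted <- !is.unsorted(o) && all(o == seq_along(o))
  gr
}

#' Write a GRanges to BED
#'
#' Emits BED3 (or BED6 when `name`/`score` columns are present) with
#' 0-based half-open coordinates; round-trips `read_bed` output bit-exactly.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @param header optional comment line(s) written with a leading `#`.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  if (!length(gr)) return(invisible(path))
  cols <- list(as.character(seqnames(gr)), bed_start(gr), bed_end(gr))
  has_name <- "name" %in% names(mcols(gr))
  has_score <- "score" %in% names(mcols(gr))
  if (has_name || has_score) {
    nm <- if (has_name) as.character(mcols(gr)$name) else rep(".", length(gr))
    nm[is.na(nm)] <- "."
    cols <- c(cols, list(nm))
    if (has_score) {
      sc <- mcols(gr)$score
      sc <- ifelse(is.na(sc), ".", format(sc, trim = TRUE, scientific = FALSE))
      cols <- c(cols, list(sc), list(rep(".", length(gr))))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#' @param path path to a `chrom<TAB>length` file.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "integer"))
  if (any(df$size <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(df$chrom)) stop("duplicated chromosome name in ", path)
  setNames(df$size, df$chrom)
}

#' Load a genome (chromosome sizes, optionally sequence)
#'
#' @param chrom_sizes named integer vector, or path to a chrom.sizes file.
#' @param fasta optional path to a genome FASTA; sequence lengths must match
#'   declared sizes.
#' @return Object of class `Genome`: list with `sizes` (named integer) and
#'   `seq` (`DNAStringSet` or `NULL`).
#' @export
load_genome <- function(chrom_sizes = NULL, fasta = NULL) {
  seqs <- NULL
  if (!is.null(fasta)) {
    seqs <- Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  }
  if (is.null(chrom_sizes)) {
    if (is.null(seqs)) stop("need chrom_sizes and/or fasta")
    sizes <- setNames(Biostrings::width(seqs), names(seqs))
  } else {
    sizes <- if (is.character(chrom_sizes) && length(chrom_sizes) == 1L &&
                 file.exists(chrom_sizes)) read_chrom_sizes(chrom_sizes)
             else chrom_sizes
    if (!is.null(seqs)) {
      common <- intersect(names(sizes), names(seqs))
      if (!length(common)) stop("no chromosome shared between sizes and FASTA")
      mism <- common[Biostrings::width(seqs[common]) != sizes[common]]
      if (length(mism))
        stop("FASTA length differs from declared size for: ",
             paste(mism, collapse = ", "))
    }
  }
  structure(list(sizes = sizes, seq = seqs), class = "Genome")
}

#' Report chromosome names absent from a genome
#'
#' Names are matched as exact strings; no `chr` aliasing is attempted, so a
#' `chr1` / `1` mismatch is reported rather than silently reconciled.
#'
#' @param gr a `GRanges`.
#' @param genome a `Genome`.
#' @return Character vector of offending names (empty when all match).
#' @export
validate_chroms <- function(gr, genome) {
  setdiff(unique(as.character(seqnames(gr))), names(genome$sizes))
}

#' Merge intervals closer than a gap
#'
#' Unions intervals on the same chromosome whose separation is `<= gap` bp.
#' With `gap = 0` only truly overlapping intervals merge (abutting half-open
#' intervals stay separate) and total covered bp is unchanged.
#'
#' @param gr a `GRanges`.
#' @param gap non-negative separation (bp) at or below which to merge.
#' @return Sorted, merged `GRanges` (`metadata()$merged` set).
#' @export
merge_intervals <- function(gr, gap = 0L) {
  stopifnot(gap >= 0)
  out <- reduce(sort(granges(gr)), min.gapwidth = gap + 1L)
  metadata(out)$sorted <- TRUE
  metadata(out)$merged <- TRUE
  out
}

#' All overlapping pairs between two interval sets
#'
#' @param a,b `GRanges`.
#' @param min_bp minimum shared bases (default 1).
#' @return `data.frame` with 1-based `query` (index in `a`) and `subject`
#'   (index in `b`) columns, one row per pair sharing `>= min_bp` bases.
#' @export
overlap_query <- function(a, b, min_bp = 1L) {
  hits <- findOverlaps(a, b, minoverlap = min_bp)
  data.frame(query = queryHits(hits), subject = subjectHits(hits))
}

#' Total covered base pairs of an interval set
#' @param gr a `GRanges`.
#' @return Total bp covered after merging.
#' @export
covered_bp <- function(gr) sum(width(reduce(granges(gr))))

#' Read gene annotation (BED or GTF) into a TSS table
#'
#' Consumes gene id, gene body, and strand; the transcription start site is
#' the body start on `+` and the body end on `-`. BED input uses column 4 as
#' the gene id. GTF input uses `gene`-type records (fallback: `transcript`)
#' and the `gene_id` attribute.
#'
#' @param path BED6 or GTF file.
#' @return `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open body), `strand`, `tss` (0-based position).
#' @export
read_gene_annotation <- function(path) {
  first <- readLines(path, n = 50L)
  is_gtf <- any(grepl("\t(gene|transcript|exon)\t", first))
  if (is_gtf) {
    df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                     quote = "", stringsAsFactors = FALSE)
    df <- df[df$V3 %in% c("gene", "transcript"), , drop = FALSE]
    if (any(df$V3 == "gene")) df <- df[df$V3 == "gene", , drop = FALSE]
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", df$V9)
    ann <- data.frame(gene_id = gid, chrom = df$V1,
                      start = df$V4 - 1L, end = df$V5,
                      strand = df$V7, stringsAsFactors = FALSE)
  } else {
    gr <- read_bed(path)
    strand6 <- {
      lines <- readLines(path)
      lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))]
      f <- strsplit(lines, "\t", fixed = TRUE)
      vapply(f, function(x) if (length(x) >= 6) x[[6]] else "+", "")
    }
    ann <- data.frame(gene_id = as.character(mcols(gr)$name),
                      chrom = as.character(seqnames(gr)),
                      start = bed_start(gr), end = bed_end(gr),
                      strand = strand6, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ann$gene_id))
    ann <- ann[!duplicated(ann$gene_id), , drop = FALSE]
  ann$strand[!ann$strand %in% c("+", "-")] <- "+"
  ann$tss <- ifelse(ann$strand == "+", ann$start, ann$end - 1L)
  rownames(ann) <- NULL
  ann
}

# Run expr with a private, restorable RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
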