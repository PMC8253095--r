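# PWM scanning over region sequences and motif-enrichment z-scores of
# foreground regions against a length-matched shuffled background.
#
# The z statistic is a two-proportion z of per-region hit frequencies against
# the background frequency. It preserves enrichment ranking semantics (which
# motifs dominate a region class) and is fully specified here; it is not the
# statistic of any external motif tool.

#' Read JASPAR-format PWMs
#'
#' Accepts JASPAR text blocks (`>id name` header, then four `A/C/G/T [ .. ]`
#' count rows). Counts are converted to per-position probabilities with a
#' pseudocount.
#'
#' @param path JASPAR-format file.
#' @param pseudocount added to every count before normalisation (default 0.01).
#' @param background base frequencies (default uniform 0.25).
#' @return Named list of `PWM` objects: `list(id, mat, bg)` where `mat` is a
#'   4 x L probability matrix with rownames A,C,G,T (columns sum to 1).
#' @export
read_jaspar <- function(path, pseudocount = 0.01,
                        background = c(A = .25, C = .25, G = .25, T = .25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no JASPAR headers ('>') found in ", path)
  bounds <- c(hdr, length(lines) + 1L)
  pwms <- lapply(seq_along(hdr), function(i) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    id <- sub("^>\\s*", "", lines[hdr[i]])
    id <- strsplit(id, "\\s+")[[1]][1]
    rows <- lapply(block, function(l) {
      base <- sub("^\\s*([ACGT]).*$", "\\1", l)
      nums <- gsub("[][ACGTacgt]", " ", l)
      vals <- as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
      list(base = base, vals = vals)
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop("PWM block for ", id, " lacks the four A/C/G/T rows")
    mat <- do.call(rbind, lapply(rows, `[[`, "vals"))
    rownames(mat) <- bases
    mat <- mat[c("A", "C", "G", "T"), , drop = FALSE]
    pwm_from_counts(mat, id = id, pseudocount = pseudocount,
                    background = background)
  })
  setNames(pwms, vapply(pwms, `[[`, "", "id"))
}

#' Build a PWM from a count (or probability) matrix
#' @param mat 4 x L matrix, rownames A,C,G,T.
#' @param id motif identifier.
#' @param pseudocount added before column normalisation.
#' @param background base frequencies.
#' @return `PWM` object.
#' @export
pwm_from_counts <- function(mat, id, pseudocount = 0.01,
                            background = c(A = .25, C = .25, G = .25, T = .25)) {
  stopifnot(nrow(mat) == 4, all(rownames(mat) == c("A", "C", "G", "T")))
  mat <- mat + pseudocount
  mat <- sweep(mat, 2L, colSums(mat), "/")
  structure(list(id = id, mat = mat, bg = background), class = "PWM")
}

# log2-odds lookup table of a PWM: 4 x L
pwm_logodds <- function(pwm) log2(pwm$mat / pwm$bg[rownames(pwm$mat)])

# per-offset forward-strand log2-odds scores; windows containing non-ACGT
# bases score NA (skipped)
pwm_scores <- function(seq_chars_idx, lut) {
  L <- ncol(lut)
  S <- length(seq_chars_idx)
  if (S < L) return(numeric(0))
  noff <- S - L + 1L
  sc <- numeric(noff)
  bad <- logical(noff)
  for (j in seq_len(L)) {
    idx <- seq_chars_idx[j:(j + noff - 1L)]
    miss <- is.na(idx)
    bad <- bad | miss
    idx[miss] <- 1L
    sc <- sc + lut[cbind(idx, j)]
  }
  sc[bad] <- NA_real_
  sc
}

seq_to_idx <- function(s) {
  match(strsplit(toupper(s), "")[[1]], c("A", "C", "G", "T"))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores each offset by the summed log2 odds `log2(p_base / bg_base)`; a hit
#' is an offset whose score reaches `score_fraction` of the maximum attainable
#' score. If the maximum attainable score is not positive (e.g. a uniform
#' PWM), no offsets are hits. Windows containing non-ACGT bases are skipped.
#' Reverse-strand matches are found by scanning the reverse complement and
#' reported as 1-based start positions of the motif window on the forward
#' strand.
#'
#' @param sequence character DNA string.
#' @param pwm a `PWM`.
#' @param score_fraction hit threshold as a fraction of the maximum
#'   attainable log2-odds score, in `(0, 1]` (default 0.8).
#' @return List with `forward` and `reverse` integer positions (1-based
#'   forward-strand window starts) and `max_score`.
#' @export
scan_pwm <- function(sequence, pwm, score_fraction = 0.8) {
  stopifnot(score_fraction > 0, score_fraction <= 1)
  lut <- pwm_logodds(pwm)
  L <- ncol(lut)
  if (nchar(sequence) < L)
    stop("sequence shorter than the motif")
  max_score <- sum(apply(lut, 2L, max))
  empty <- list(forward = integer(0), reverse = integer(0),
                max_score = max_score)
  if (max_score <= 0) return(empty)
  thr <- score_fraction * max_score
  fwd_sc <- pwm_scores(seq_to_idx(sequence), lut)
  rev_sc <- pwm_scores(seq_to_idx(revcomp_chr(sequence)), lut)
  fwd <- which(!is.na(fwd_sc) & fwd_sc >= thr)
  rev_on_rc <- which(!is.na(rev_sc) & rev_sc >= thr)
  # position i on the reverse complement corresponds to forward-strand
  # window start S - L - i + 2 (1-based)
  S <- nchar(sequence)
  rev <- sort(S - L - rev_on_rc + 2L)
  list(forward = fwd, reverse = rev, max_score = max_score)
}

#' Extract region sequences from a genome
#' @param regions `GRanges`.
#' @param genome a `Genome` with sequence loaded.
#' @return Character vector of region sequences.
#' @export
region_sequences <- function(regions, genome) {
  if (is.null(genome$seq)) stop("genome sequence not loaded")
  vapply(seq_along(regions), function(i) {
    ch <- as.character(seqnames(regions))[i]
    as.character(Biostrings::subseq(genome$seq[[ch]],
                                    start = start(regions)[i],
                                    end = end(regions)[i]))
  }, character(1))
}

#' Motif enrichment z-scores of foreground vs background regions
#'
#' For each PWM, computes the fraction of foreground and background regions
#' carrying at least one hit and the two-proportion z
#' `z = (f_fg - f_bg) / sqrt(f_bg (1 - f_bg) / n_fg)`, with `f_bg` clamped to
#' `[1/(2 n_bg), 1 - 1/(2 n_bg)]` to avoid zero division. The background is
#' intended to be a [matched_shuffle()] of the foreground (same lengths).
#'
#' @param fg,bg `GRanges` of foreground and background regions
#'   (each >= 20 regions).
#' @param genome a `Genome` with sequence.
#' @param pwms named list of `PWM` objects.
#' @param score_fraction hit threshold fraction (default 0.8).
#' @param top_n number of rows reported (default 15).
#' @return `data.frame` ranked by decreasing `z` with columns `motif_id`,
#'   `f_fg`, `f_bg`, `z`, `n_fg`, `n_bg`; full table in `attr(, "all")`.
#' @export
motif_enrichment_z <- function(fg, bg, genome, pwms, score_fraction = 0.8,
                               top_n = 15L) {
  if (is.null(genome$seq)) stop("genome sequence not loaded")
  stopifnot(length(fg) >= 20, length(bg) >= 20)
  fg_seq <- region_sequences(fg, genome)
  bg_seq <- region_sequences(bg, genome)
  n_fg <- length(fg_seq); n_bg <- length(bg_seq)
  has_hit <- function(seqs, pwm) {
    vapply(seqs, function(s) {
      if (nchar(s) < ncol(pwm$mat)) return(FALSE)
      h <- scan_pwm(s, pwm, score_fraction)
      length(h$forward) + length(h$reverse) > 0
    }, logical(1), USE.NAMES = FALSE)
  }
  rows <- lapply(pwms, function(p) {
    f_fg <- mean(has_hit(fg_seq, p))
    f_bg_raw <- mean(has_hit(bg_seq, p))
    f_bg <- min(max(f_bg_raw, 1 / (2 * n_bg)), 1 - 1 / (2 * n_bg))
    z <- (f_fg - f_bg) / sqrt(f_bg * (1 - f_bg) / n_fg)
    data.frame(motif_id = p$id, f_fg = f_fg, f_bg = f_bg_raw, z = z,
               n_fg = n_fg, n_bg = n_bg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$z, out$motif_id), ]
  rownames(out) <- NULL
  top <- head(out, top_n)
  attr(top, "all") <- out
  top
}
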