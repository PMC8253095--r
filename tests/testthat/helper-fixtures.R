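# Shared fixtures: everything is built in code at test time.

toy_genome <- function(sizes = c(chr1 = 10000L, chr2 = 8000L)) {
  structure(list(sizes = sizes, seq = NULL), class = "Genome")
}

# random interval set on a toy genome (0-based half-open coordinates)
random_intervals <- function(n, sizes = c(chr1 = 10000L, chr2 = 8000L),
                             max_width = 200L) {
  ch <- sample(names(sizes), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s0 <- vapply(seq_len(n),
               function(i) sample.int(sizes[[ch[i]]] - w[i], 1L) - 1L,
               integer(1))
  gintervals(ch, s0, s0 + w)
}

# brute-force all-pairs overlap scan (independent of IRanges)
brute_force_overlaps <- function(a, b, min_bp = 1L) {
  out <- list()
  for (i in seq_along(a)) for (j in seq_along(b)) {
    if (as.character(seqnames(a))[i] != as.character(seqnames(b))[j]) next
    ov <- min(bed_end(a)[i], bed_end(b)[j]) -
      max(bed_start(a)[i], bed_start(b)[j])
    if (ov >= min_bp) out[[length(out) + 1L]] <- c(i, j)
  }
  if (!length(out)) return(data.frame(query = integer(0), subject = integer(0)))
  m <- do.call(rbind, out)
  data.frame(query = m[, 1], subject = m[, 2])
}

write_tmp_bed <- function(lines) {
  path <- tempfile(fileext = ".bed")
  writeLines(lines, path)
  path
}

# a small simulated study shared across test files (built once per run)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "cistromics_small_sim")
      unlink(dir, recursive = TRUE)
      cfg <- sim_config(seed = 101L, n_chroms = 2L, chrom_length = 4e5,
                        n_genes = 80L, n_core_peaks = 120L,
                        n_specific_per_sample = 30L)
      cache <<- simulate_dataset(cfg, dir)
    }
    cache
  }
})
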