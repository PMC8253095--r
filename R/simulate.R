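# Deterministic generator of a complete toy multi-cistrome study: genome,
# TSS annotation, dual-caller peak BEDs for 4 samples x 5 factors, fragment
# BEDs, PWM library with a planted motif, gene sets, and an expression matrix
# with planted differential genes. All randomness flows from one seed through
# named substreams so components can be regenerated independently.

#' Simulation configuration
#'
#' Defaults encode the study structure the pipeline is designed for: four
#' clonally related samples sharing a large core cistrome per factor plus
#' small sample-specific sets; stronger signal at core sites; an active
#' histone mark present at all core sites (and at a planted "active" fraction
#' of sample-specific sites) irrespective of factor occupancy; a motif
#' planted preferentially in core sites; and a four-sample expression matrix
#' in which exactly `n_de_genes` genes differ between the two 2-sample
#' groups.
#'
#' @param seed master seed; all substreams derive from it.
#' @param n_chroms,chrom_length genome shape (default 3 x 1 Mb).
#' @param n_genes number of genes (default 200).
#' @param n_samples number of samples (default 4; groups split in half).
#' @param n_core_peaks shared core peaks per factor (default 500).
#' @param n_specific_per_sample sample-specific peaks per factor (default 100).
#' @param peak_width_meanlog,peak_width_sdlog log-normal peak widths
#'   (median 300 bp).
#' @param core_multiplier signal multiplier of core over specific sites
#'   (default 3).
#' @param bg_frag_rate background fragments per bp per track (default 0.005).
#' @param peak_frags_mean mean fragments per specific peak (default 30).
#' @param motif_prob_core,motif_prob_specific planting probabilities of the
#'   motif in core / specific AR sites (defaults 0.8 / 0.3).
#' @param active_fraction fraction of sample-specific AR sites carrying the
#'   active mark (default 0.5).
#' @param n_de_genes,de_log2fc planted differential genes and their effect
#'   (defaults 2 genes at |log2FC| = 3).
#' @param nb_dispersion NB dispersion of expression counts (default 0.05).
#' @param read_length single-end read length in bp (default 65).
#' @param caller2_jitter,caller2_dropout caller-2 peak jitter (+/- bp) and
#'   dropout fraction (defaults 50 bp, 5%).
#' @return `SimulationConfig` list.
#' @export
sim_config <- function(seed = 1L, n_chroms = 3L, chrom_length = 1e6,
                       n_genes = 200L, n_samples = 4L,
                       n_core_peaks = 500L, n_specific_per_sample = 100L,
                       peak_width_meanlog = log(300), peak_width_sdlog = 0.35,
                       core_multiplier = 3, bg_frag_rate = 0.005,
                       peak_frags_mean = 30, motif_prob_core = 0.8,
                       motif_prob_specific = 0.3, active_fraction = 0.5,
                       n_de_genes = 2L, de_log2fc = 3, nb_dispersion = 0.05,
                       read_length = 65L, caller2_jitter = 50L,
                       caller2_dropout = 0.05) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_samples >= 2, cfg$n_samples %% 2 == 0,
            cfg$active_fraction >= 0, cfg$active_fraction <= 1,
            cfg$motif_prob_core >= 0, cfg$motif_prob_core <= 1,
            cfg$caller2_dropout >= 0, cfg$caller2_dropout < 1)
  planted_bp <- (cfg$n_core_peaks + cfg$n_samples * cfg$n_specific_per_sample) *
    exp(cfg$peak_width_meanlog) * 1.2
  if (planted_bp > 0.5 * cfg$n_chroms * cfg$chrom_length)
    stop("genome too small for the requested peak load")
  cfg$samples <- paste0("S", seq_len(cfg$n_samples))
  cfg$group_a <- cfg$samples[seq_len(cfg$n_samples / 2)]
  cfg$group_b <- setdiff(cfg$samples, cfg$group_a)
  cfg$factors <- c("AR", "FOXA1", "CTCF", "H3K27ac", "H3K27me3")
  class(cfg) <- "SimulationConfig"
  cfg
}

# substream seeds derived once from the master seed
substream_seeds <- function(seed) {
  with_seed(seed, setNames(sample.int(.Machine$integer.max - 1L, 7L),
                           c("genome", "peaks", "caller2", "fragments",
                             "motifs", "genesets", "expression")))
}

# place n non-overlapping intervals with the given widths on the genome,
# keeping same-set intervals at least min_gap bp apart so that planted sites
# are resolvable in windowed signal views
place_disjoint <- function(n, widths, sizes, min_gap = 1000L) {
  placed_ch <- character(0); placed_s <- numeric(0); placed_e <- numeric(0)
  out_ch <- character(n); out_s <- integer(n)
  for (i in seq_len(n)) {
    w <- widths[i]
    for (att in seq_len(2000L)) {
      ch <- sample(names(sizes), 1L, prob = sizes / sum(sizes))
      s0 <- floor(runif(1) * (sizes[[ch]] - w))
      same <- placed_ch == ch
      if (!any(same & placed_s < s0 + w + min_gap & placed_e > s0 - min_gap))
        break
      if (att == 2000L) stop("could not place interval ", i)
    }
    out_ch[i] <- ch; out_s[i] <- s0
    placed_ch <- c(placed_ch, ch); placed_s <- c(placed_s, s0)
    placed_e <- c(placed_e, s0 + w)
  }
  gintervals(out_ch, out_s, out_s + widths)
}

# the planted androgen-response-element-like motif (palindrome-ish 15-mer)
planted_motif_matrix <- function() {
  consensus <- strsplit("AGAACAGCATGTTCT", "")[[1]]
  mat <- matrix(5, nrow = 4, ncol = length(consensus),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(consensus)) mat[consensus[j], j] <- 85
  mat
}

random_motif_matrix <- function(len = 15L) {
  consensus <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  mat <- matrix(5, nrow = 4, ncol = len,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_len(len)) mat[consensus[j], j] <- 85
  mat
}

write_jaspar <- function(mats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(mats)) {
    writeLines(paste0(">", nm), con)
    m <- mats[[nm]]
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, " [ ", paste(m[b, ], collapse = " "), " ]"), con)
  }
}

# Poisson fragments over enriched regions plus uniform background.
# Returns a GRanges of read_length fragments clipped to the chromosome.
simulate_fragments <- function(regions, intensities, sizes, bg_rate,
                               read_length) {
  ch_out <- character(0); s_out <- integer(0)
  if (length(regions)) {
    n_per <- rpois(length(regions), intensities)
    idx <- rep(seq_along(regions), n_per)
    if (length(idx)) {
      mid <- floor((bed_start(regions) + bed_end(regions)) / 2)[idx]
      w <- width(regions)[idx]
      centers <- round(rnorm(length(idx), mean = mid, sd = w / 4))
      s0 <- centers - floor(read_length / 2)
      ch <- as.character(seqnames(regions))[idx]
      s0 <- pmax(0L, pmin(s0, sizes[ch] - read_length))
      ch_out <- c(ch_out, ch); s_out <- c(s_out, as.integer(s0))
    }
  }
  n_bg <- rpois(1L, bg_rate * sum(sizes))
  if (n_bg > 0) {
    ch <- sample(names(sizes), n_bg, replace = TRUE, prob = sizes / sum(sizes))
    s0 <- floor(runif(n_bg) * (sizes[ch] - read_length))
    ch_out <- c(ch_out, ch); s_out <- c(s_out, as.integer(s0))
  }
  o <- order(ch_out, s_out)
  gintervals(ch_out[o], s_out[o], s_out[o] + read_length)
}

jitter_peaks <- function(gr, jitter, dropout, sizes) {
  keep <- runif(length(gr)) >= dropout
  gr <- gr[keep]
  if (!length(gr)) return(granges(gr))
  shift <- sample(seq(-jitter, jitter), length(gr), replace = TRUE)
  ch <- as.character(seqnames(gr))
  s0 <- pmax(0L, pmin(bed_start(gr) + shift, sizes[ch] - width(gr)))
  sort(gintervals(ch, s0, s0 + width(gr)))
}

#' Simulate a complete toy study with planted ground truth
#'
#' Writes, under `outdir`: `genome.fa` + `genome.chrom.sizes`; `genes.bed`
#' (gene bodies, BED6); per sample/factor caller-1 and caller-2 peak BEDs
#' (caller-2 = caller-1 jittered with dropout, so the intersection is
#' nontrivial); fragment BEDs with Poisson background plus peak-shaped
#' enrichment (core sites at `core_multiplier` x the specific intensity; the
#' active mark H3K27ac placed at all AR core sites and at the planted active
#' subset of AR sample-specific sites, regardless of AR occupancy;
#' H3K27me3 as coverage-only background); a JASPAR PWM library whose first
#' motif is planted in AR sites; a GMT with a core-linked "hallmark-like"
#' set, an essential-gene-like set, and random decoys; an expression count
#' TSV with `n_de_genes` genes split between the two sample groups; and
#' `truth.json`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created).
#' @return Invisibly, a list with `truth`, `files`, `config`.
#' @export
simulate_dataset <- function(config = sim_config(), outdir) {
  cfg <- config
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "peaks"), showWarnings = FALSE)
  dir.create(file.path(outdir, "fragments"), showWarnings = FALSE)
  seeds <- substream_seeds(cfg$seed)
  sizes <- setNames(rep(as.integer(cfg$chrom_length), cfg$n_chroms),
                    paste0("chr", seq_len(cfg$n_chroms)))

  ## peaks: per TF factor a disjoint core set + per-sample specific sets
  tf_factors <- c("AR", "FOXA1", "CTCF")
  peak_truth <- with_seed(seeds[["peaks"]], {
    lapply(setNames(tf_factors, tf_factors), function(f) {
      n_tot <- cfg$n_core_peaks + cfg$n_samples * cfg$n_specific_per_sample
      widths <- as.integer(round(rlnorm(n_tot, cfg$peak_width_meanlog,
                                        cfg$peak_width_sdlog)))
      widths <- pmax(widths, 50L)
      all_gr <- place_disjoint(n_tot, widths, sizes)
      core <- sort(all_gr[seq_len(cfg$n_core_peaks)])
      rest <- all_gr[-seq_len(cfg$n_core_peaks)]
      specific <- lapply(setNames(seq_len(cfg$n_samples), cfg$samples),
        function(s) {
          lo <- (s - 1L) * cfg$n_specific_per_sample + 1L
          sort(rest[lo:(lo + cfg$n_specific_per_sample - 1L)])
        })
      list(core = core, specific = specific)
    })
  })
  # planted active subset of AR sample-specific sites (carries H3K27ac in
  # every sample's track: the enhancer stays active whether or not AR binds)
  active <- with_seed(seeds[["peaks"]] + 2L, {
    lapply(peak_truth$AR$specific, function(gr) {
      n_act <- round(cfg$active_fraction * length(gr))
      sort(gr[sample(length(gr), n_act)])
    })
  })
  all_active <- sort(do.call(c, unname(lapply(active, granges))))

  ## genome sequence with the motif planted into AR sites
  motif_mat <- planted_motif_matrix()
  consensus <- c("A", "C", "G", "T")[apply(motif_mat, 2L, which.max)]
  mlen <- length(consensus)
  motif_placements <- list()
  genome_chars <- with_seed(seeds[["genome"]], {
    lapply(setNames(names(sizes), names(sizes)), function(ch)
      sample(c("A", "C", "G", "T"), sizes[[ch]], replace = TRUE))
  })
  motif_placements <- with_seed(seeds[["motifs"]], {
    plant <- function(gr, prob) {
      pick <- runif(length(gr)) < prob
      gr <- gr[pick]
      if (!length(gr)) return(NULL)
      mid0 <- floor((bed_start(gr) + bed_end(gr)) / 2)
      data.frame(chrom = as.character(seqnames(gr)),
                 pos = mid0 - floor(mlen / 2), stringsAsFactors = FALSE)
    }
    rbind(plant(peak_truth$AR$core, cfg$motif_prob_core),
          do.call(rbind, lapply(peak_truth$AR$specific, plant,
                                prob = cfg$motif_prob_specific)))
  })
  if (!is.null(motif_placements)) {
    for (i in seq_len(nrow(motif_placements))) {
      ch <- motif_placements$chrom[i]
      p0 <- motif_placements$pos[i]
      genome_chars[[ch]][(p0 + 1L):(p0 + mlen)] <- consensus
    }
  }
  fa_path <- file.path(outdir, "genome.fa")
  con <- file(fa_path, "w")
  for (ch in names(genome_chars)) {
    writeLines(paste0(">", ch), con)
    s <- paste(genome_chars[[ch]], collapse = "")
    writeLines(substring(s, seq(1, nchar(s), 80), pmin(seq(80, nchar(s) + 79, 80), nchar(s))), con)
  }
  close(con)
  cs_path <- file.path(outdir, "genome.chrom.sizes")
  writeLines(paste(names(sizes), sizes, sep = "\t"), cs_path)

  ## PWM library: planted motif first, then decoys
  pwm_mats <- with_seed(seeds[["motifs"]] + 1L, {
    decoys <- lapply(seq_len(9L), function(i) random_motif_matrix(mlen))
    c(list(PLANTED_ARE = motif_mat),
      setNames(decoys, paste0("DECOY_", seq_len(9L))))
  })
  pwm_path <- file.path(outdir, "pwms.jaspar")
  write_jaspar(pwm_mats, pwm_path)

  ## genes
  genes <- with_seed(seeds[["genome"]] + 1L, {
    w <- as.integer(round(runif(cfg$n_genes, 2000, 10000)))
    ch <- sample(names(sizes), cfg$n_genes, replace = TRUE,
                 prob = sizes / sum(sizes))
    s0 <- floor(runif(cfg$n_genes) * (sizes[ch] - w))
    data.frame(gene_id = sprintf("G%03d", seq_len(cfg$n_genes)),
               chrom = ch, start = as.integer(s0), end = as.integer(s0 + w),
               strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes_path <- file.path(outdir, "genes.bed")
  writeLines(paste(genes$chrom, genes$start, genes$end, genes$gene_id, 0,
                   genes$strand, sep = "\t"), genes_path)

  ## gene sets: core-linked hallmark-like + essential-like + decoys
  ann <- genes[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
  core_linked <- link_regions_to_genes(peak_truth$AR$core, ann,
                                       window = 20000L)$genes
  gene_sets <- with_seed(seeds[["genesets"]], {
    pick <- function(pool, n) sample(pool, min(n, length(pool)))
    hall <- unique(c(pick(core_linked, round(0.6 * length(core_linked))),
                     pick(genes$gene_id, 5)))
    ess <- unique(c(pick(core_linked, round(0.5 * length(core_linked))),
                    pick(genes$gene_id, 8)))
    decoys <- lapply(seq_len(8L), function(i) pick(genes$gene_id, 20))
    c(list(HALLMARK_CORE_LIKE = hall, ESSENTIAL_LIKE = ess),
      setNames(decoys, paste0("RANDOM_SET_", seq_len(8L))))
  })
  gmt_path <- file.path(outdir, "gene_sets.gmt")
  writeLines(vapply(names(gene_sets), function(nm)
    paste(c(nm, "synthetic", gene_sets[[nm]]), collapse = "\t"), ""),
    gmt_path)

  ## peak BED files (two callers) and fragment BED files
  peak_files <- list(); frag_files <- list()
  intensity_rows <- list()
  spec_int <- cfg$peak_frags_mean
  core_int <- cfg$core_multiplier * cfg$peak_frags_mean
  for (s in cfg$samples) {
    enriched_by_factor <- list(
      AR = list(regions = c(peak_truth$AR$core, peak_truth$AR$specific[[s]]),
                intensity = c(rep(core_int, length(peak_truth$AR$core)),
                              rep(spec_int, length(peak_truth$AR$specific[[s]])))),
      FOXA1 = list(regions = c(peak_truth$FOXA1$core,
                               peak_truth$FOXA1$specific[[s]]),
                   intensity = c(rep(core_int, length(peak_truth$FOXA1$core)),
                                 rep(spec_int, length(peak_truth$FOXA1$specific[[s]])))),
      CTCF = list(regions = c(peak_truth$CTCF$core,
                              peak_truth$CTCF$specific[[s]]),
                  intensity = c(rep(core_int, length(peak_truth$CTCF$core)),
                                rep(spec_int, length(peak_truth$CTCF$specific[[s]])))),
      H3K27ac = list(regions = c(peak_truth$AR$core, all_active),
                     intensity = c(rep(core_int, length(peak_truth$AR$core)),
                                   rep(2 * spec_int, length(all_active)))),
      H3K27me3 = list(regions = GRanges(), intensity = numeric(0)))
    for (f in cfg$factors) {
      enr <- enriched_by_factor[[f]]
      frags <- with_seed(seeds[["fragments"]] + match(s, cfg$samples) * 100L +
                           match(f, cfg$factors), {
        simulate_fragments(enr$regions, enr$intensity, sizes,
                           cfg$bg_frag_rate, cfg$read_length)
      })
      fp <- file.path(outdir, "fragments", paste0(s, "_", f, ".bed"))
      write_bed(frags, fp)
      frag_files[[paste(s, f, sep = "_")]] <- fp
      if (f != "H3K27me3") {
        c1 <- sort(enr$regions)
        c2 <- with_seed(seeds[["caller2"]] + match(s, cfg$samples) * 100L +
                          match(f, cfg$factors), {
          jitter_peaks(c1, cfg$caller2_jitter, cfg$caller2_dropout, sizes)
        })
        p1 <- file.path(outdir, "peaks", paste0(s, "_", f, "_caller1.bed"))
        p2 <- file.path(outdir, "peaks", paste0(s, "_", f, "_caller2.bed"))
        write_bed(c1, p1); write_bed(c2, p2)
        peak_files[[paste(s, f, "caller1", sep = "_")]] <- p1
        peak_files[[paste(s, f, "caller2", sep = "_")]] <- p2
      }
      intensity_rows[[paste(s, f, sep = "_")]] <-
        data.frame(sample = s, factor = f, n_regions = length(enr$regions),
                   mean_intensity = if (length(enr$intensity))
                     mean(enr$intensity) else 0)
    }
  }

  ## expression counts with planted DE genes
  expr <- with_seed(seeds[["expression"]], {
    base <- rlnorm(cfg$n_genes, meanlog = log(100), sdlog = 1)
    eligible <- which(base >= 50)
    de_idx <- sample(eligible, cfg$n_de_genes)
    mu <- matrix(base, nrow = cfg$n_genes, ncol = cfg$n_samples,
                 dimnames = list(genes$gene_id, cfg$samples))
    for (j in seq_along(de_idx)) {
      g <- de_idx[j]
      sgn <- if (j %% 2 == 1) 1 else -1
      mu[g, cfg$group_a] <- base[g] * 2^(-sgn * cfg$de_log2fc / 2)
      mu[g, cfg$group_b] <- base[g] * 2^(sgn * cfg$de_log2fc / 2)
    }
    libfac <- exp(rnorm(cfg$n_samples, 0, 0.15))
    counts <- matrix(rnbinom(length(mu),
                             mu = sweep(mu, 2L, libfac, "*"),
                             size = 1 / cfg$nb_dispersion),
                     nrow = cfg$n_genes, dimnames = dimnames(mu))
    list(counts = counts, de_genes = genes$gene_id[de_idx], libfac = libfac)
  })
  counts_path <- file.path(outdir, "expression_counts.tsv")
  write.table(data.frame(gene_id = rownames(expr$counts), expr$counts,
                         check.names = FALSE),
              counts_path, sep = "\t", quote = FALSE, row.names = FALSE)

  gr_to_df <- function(gr) data.frame(chrom = as.character(seqnames(gr)),
                                      start = bed_start(gr), end = bed_end(gr))
  truth <- list(
    samples = cfg$samples, group_a = cfg$group_a, group_b = cfg$group_b,
    factors = cfg$factors,
    shared_fraction = cfg$n_core_peaks /
      (cfg$n_core_peaks + cfg$n_specific_per_sample),
    core = lapply(peak_truth, function(x) gr_to_df(x$core)),
    specific = lapply(peak_truth, function(x) lapply(x$specific, gr_to_df)),
    active_specific = lapply(active, gr_to_df),
    planted_motif = "PLANTED_ARE",
    n_motif_placements = if (is.null(motif_placements)) 0L
                         else nrow(motif_placements),
    de_genes = expr$de_genes,
    intensities = do.call(rbind, intensity_rows))
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")

  files <- list(genome_fasta = fa_path, chrom_sizes = cs_path,
                genes = genes_path, gene_sets = gmt_path, pwms = pwm_path,
                counts = counts_path, truth = truth_path,
                peaks = peak_files, fragments = frag_files)
  invisible(list(truth = truth, files = files, config = cfg,
                 peak_truth = peak_truth, active = active))
}

# bp-level Jaccard of two interval sets
interval_jaccard <- function(a, b) {
  a <- reduce(granges(a)); b <- reduce(granges(b))
  u <- sum(width(GenomicRanges::union(a, b)))
  if (u == 0) return(NA_real_)
  sum(width(GenomicRanges::intersect(a, b))) / u
}

#' Compare pipeline results with planted truth
#'
#' @param results list with any of: `membership` (a [build_membership()]
#'   result on AR consensus peaks), `selected_active` (named list of
#'   `GRanges`, per sample), `motif_table` (from [motif_enrichment_z()]),
#'   `de` (from [differential_expression()]).
#' @param truth the `truth` element returned by [simulate_dataset()].
#' @return List of recovery metrics: `shared_fraction`,
#'   `shared_fraction_error`, `specific_jaccard`, `active_jaccard`,
#'   `motif_rank`, `de_precision`, `de_recall`.
#' @export
truth_compare <- function(results, truth) {
  df_to_gr <- function(df) gintervals(df$chrom, df$start, df$end)
  out <- list()
  if (!is.null(results$membership)) {
    m <- results$membership
    have <- colnames(m$occupancy)
    if (length(setdiff(have, truth$samples)))
      stop("sample ids in membership do not match truth: ",
           paste(setdiff(have, truth$samples), collapse = ", "))
    out$shared_fraction <- m$shared_fraction
    out$shared_fraction_error <- m$shared_fraction - truth$shared_fraction
    spec_j <- vapply(have, function(s) {
      rec <- membership_regions(m, paste0("specific:", s))
      interval_jaccard(rec, df_to_gr(truth$specific$AR[[s]]))
    }, numeric(1))
    out$specific_jaccard <- mean(spec_j)
  }
  if (!is.null(results$selected_active)) {
    act_j <- vapply(names(results$selected_active), function(s) {
      interval_jaccard(results$selected_active[[s]],
                       df_to_gr(truth$active_specific[[s]]))
    }, numeric(1))
    out$active_jaccard <- mean(act_j)
  }
  if (!is.null(results$motif_table)) {
    tab <- attr(results$motif_table, "all")
    if (is.null(tab)) tab <- results$motif_table
    out$motif_rank <- match(truth$planted_motif, tab$motif_id)
  }
  if (!is.null(results$de)) {
    called <- results$de$gene_id[results$de$pass]
    tp <- length(intersect(called, truth$de_genes))
    out$de_precision <- if (length(called)) tp / length(called) else NA_real_
    out$de_recall <- tp / length(truth$de_genes)
    out$de_called <- called
  }
  out
}
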