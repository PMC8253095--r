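# End-to-end orchestration: QC -> consensus -> membership -> noise ->
# quantify -> stratify -> annotate/enrich -> motifs -> transcriptome ->
# concordance -> report. Every stage logs its parameters; fixed seeds make
# reruns deterministic.

#' Default pipeline parameters
#'
#' @return Named list: `min_peaks` (absolute QC floor, 10000), `window`
#'   (peak-to-gene TSS window, 20 kb), `flank`/`flank_wide` (signal-matrix
#'   half-windows, 2 kb / 5 kb), `bin_size` (25 bp), `strat_flank`
#'   (half-window of the site-proximal matrix used for stratification,
#'   500 bp), `k`/`n_top` (k-means strata, 3 / top 2; selecting the top two
#'   clusters assumes the mark-positive population spans at most two, so `k`
#'   exceeds it by one), `kmeans_seed` (1729), `de_fdr` (0.05), `de_lfc` (2),
#'   `expr_floor` (4), `promoter_flank` (1 kb), `score_fraction` (0.8),
#'   `top_sets` (12), `top_motifs` (15), `seed` (1).
#' @export
default_params <- function() {
  list(min_peaks = 10000L, window = 20000L, flank = 2000L,
       flank_wide = 5000L, bin_size = 25L, k = 3L, n_top = 2L,
       strat_flank = 500L, kmeans_seed = 1729L,
       de_fdr = 0.05, de_lfc = 2, expr_floor = 4,
       promoter_flank = 1000L, score_fraction = 0.8, top_sets = 12L,
       top_motifs = 15L, seed = 1L)
}

#' Load a pipeline run configuration from YAML
#'
#' The YAML must provide a `samples` list (each with `sample`, `factor`,
#' `caller1`, `caller2`, `fragments` paths; peak-less coverage factors may
#' omit the caller files), file paths (`chrom_sizes`, optionally
#' `genome_fasta`, `genes`, `gene_sets`, `pwms`, `counts`), optional
#' `group_a`/`group_b` sample lists, and an optional `params` block
#' overriding [default_params()].
#'
#' @param path YAML file.
#' @return Validated `RunConfig` list.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  samples <- do.call(rbind, lapply(y$samples, function(s)
    data.frame(sample = s$sample, factor = s$factor,
               caller1 = s$caller1 %||% NA_character_,
               caller2 = s$caller2 %||% NA_character_,
               fragments = s$fragments, stringsAsFactors = FALSE)))
  cfg <- list(samples = samples,
              chrom_sizes = y$chrom_sizes, genome_fasta = y$genome_fasta,
              genes = y$genes, gene_sets = y$gene_sets, pwms = y$pwms,
              counts = y$counts, group_a = unlist(y$group_a),
              group_b = unlist(y$group_b),
              params = utils::modifyList(default_params(), y$params %||% list()))
  validate_run_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a run configuration
#' @param cfg `RunConfig` list.
#' @return `cfg`, with class set, or an error naming the missing file.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.data.frame(cfg$samples), nrow(cfg$samples) >= 1)
  paths <- c(stats::na.omit(cfg$samples$caller1),
             stats::na.omit(cfg$samples$caller2),
             cfg$samples$fragments, cfg$chrom_sizes,
             unlist(cfg[c("genome_fasta", "genes", "gene_sets",
                          "pwms", "counts")]))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  cfg$params <- utils::modifyList(default_params(), cfg$params %||% list())
  class(cfg) <- "RunConfig"
  cfg
}

#' Build a run configuration from a simulated dataset
#'
#' @param ds return value of [simulate_dataset()] (or the path to its
#'   output directory).
#' @param params overrides of [default_params()]; at the toy scale of the
#'   default simulation the absolute QC floor is set to 100 peaks (the
#'   quantile fence is scale-free and unchanged).
#' @return `RunConfig`.
#' @export
config_from_dataset <- function(ds, params = list(min_peaks = 100L)) {
  if (is.character(ds)) {
    dir <- ds
    truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                                 simplifyVector = TRUE)
    samples <- truth$samples; factors <- truth$factors
    group_a <- truth$group_a; group_b <- truth$group_b
  } else {
    dir <- dirname(ds$files$genome_fasta)
    samples <- ds$config$samples; factors <- ds$config$factors
    group_a <- ds$config$group_a; group_b <- ds$config$group_b
  }
  rows <- do.call(rbind, lapply(samples, function(s)
    do.call(rbind, lapply(factors, function(f) {
      p1 <- file.path(dir, "peaks", paste0(s, "_", f, "_caller1.bed"))
      data.frame(sample = s, factor = f,
                 caller1 = if (file.exists(p1)) p1 else NA_character_,
                 caller2 = if (file.exists(p1))
                   file.path(dir, "peaks", paste0(s, "_", f, "_caller2.bed"))
                   else NA_character_,
                 fragments = file.path(dir, "fragments",
                                       paste0(s, "_", f, ".bed")),
                 stringsAsFactors = FALSE)
    }))))
  validate_run_config(list(
    samples = rows, chrom_sizes = file.path(dir, "genome.chrom.sizes"),
    genome_fasta = file.path(dir, "genome.fa"),
    genes = file.path(dir, "genes.bed"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    pwms = file.path(dir, "pwms.jaspar"),
    counts = file.path(dir, "expression_counts.tsv"),
    group_a = group_a, group_b = group_b,
    params = utils::modifyList(default_params(), params)))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full cistrome concordance pipeline
#'
#' Stages run in dependency order: per-sample dual-caller intersection;
#' peak-count QC (excluded sample/factor tracks are dropped from all
#' downstream stages); cross-sample membership decomposition per factor;
#' length-matched noise regions per factor; fragment counting and rank-sum
#' contrasts of shared / specific / noise log counts; k-means stratification
#' of sample-specific AR sites by matched-sample H3K27ac signal; genomic
#' context, TSS-window gene linkage and hypergeometric gene-set enrichment of
#' the active sites; PWM enrichment of shared sites against a shuffled
#' background; expression normalisation, filtering and two-group NB Wald
#' differential expression; and correlation/complete-linkage concordance of
#' all ChIP tracks and of expression. All tabular outputs are written under
#' `outdir`; parameters and seeds are echoed to `run_log.txt`.
#'
#' @param cfg a `RunConfig` from [load_run_config()] or
#'   [config_from_dataset()].
#' @param outdir report directory (created).
#' @param stratify_factor factor whose sample-specific sites are stratified
#'   (default `"AR"`).
#' @param mark_factor active mark used for stratification
#'   (default `"H3K27ac"`).
#' @return List with elements `qc`, `consensus`, `membership`, `noise`,
#'   `ranksum`, `strata`, `selected_active`, `context`, `links`,
#'   `enrichment`, `motif_table`, `size_factors`, `de`, `chip_correlation`,
#'   `chip_dendrogram`, `expr_correlation`, `outdir`.
#' @export
run_pipeline <- function(cfg, outdir, stratify_factor = "AR",
                         mark_factor = "H3K27ac") {
  stopifnot(inherits(cfg, "RunConfig"))
  p <- cfg$params
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run_log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("cistromics run %s", format(Sys.time(), "%Y-%m-%d"))
  for (nm in names(p)) logf("param %s = %s", nm, paste(p[[nm]], collapse = ","))
  genome <- load_genome(chrom_sizes = cfg$chrom_sizes,
                        fasta = cfg$genome_fasta)
  st <- cfg$samples
  has_peaks <- !is.na(st$caller1)

  ## stage: consensus (dual-caller intersection per track)
  consensus <- list()
  for (i in which(has_peaks)) {
    key <- paste(st$sample[i], st$factor[i], sep = "_")
    consensus[[key]] <- intersect_caller_peaks(read_bed(st$caller1[i]),
                                               read_bed(st$caller2[i]))
  }
  logf("stage consensus: %d tracks intersected", length(consensus))

  ## stage: QC per factor on consensus peak counts
  qc_rows <- list()
  excluded <- character(0)
  for (f in unique(st$factor[has_peaks])) {
    keys <- paste(st$sample[has_peaks & st$factor == f], f, sep = "_")
    counts <- setNames(vapply(consensus[keys], length, integer(1)),
                       st$sample[has_peaks & st$factor == f])
    rep <- qc_filter(counts, min_peaks = p$min_peaks)
    rep$factor <- f
    qc_rows[[f]] <- rep
    excluded <- c(excluded, paste(rep$sample[rep$excluded], f, sep = "_"))
  }
  qc <- do.call(rbind, qc_rows); rownames(qc) <- NULL
  write_tsv(qc, file.path(outdir, "qc.tsv"))
  logf("stage qc: %d track(s) excluded (%s)", length(excluded),
       paste(excluded, collapse = ", "))
  consensus <- consensus[setdiff(names(consensus), excluded)]

  ## stage: membership per factor
  membership <- list(); noise <- list()
  mem_rows <- list()
  for (f in unique(st$factor[has_peaks])) {
    ss <- st$sample[has_peaks & st$factor == f]
    keys <- paste(ss, f, sep = "_")
    keep <- keys %in% names(consensus)
    if (sum(keep) < 2) next
    ps <- setNames(consensus[keys[keep]], ss[keep])
    membership[[f]] <- build_membership(ps)
    regions <- membership[[f]]$regions
    mcols(regions)$name <- membership[[f]]$class
    write_bed(regions, file.path(outdir, paste0("consensus_", f, ".bed")))
    mem_rows[[f]] <- data.frame(factor = f,
                                pattern = names(membership[[f]]$class_counts),
                                n = membership[[f]]$class_counts)
    ## stage: noise (length-matched shuffle, concatenated peaks excluded)
    concat <- do.call(c, lapply(unname(ps), granges))
    noise[[f]] <- matched_shuffle(concat, genome, exclusion = concat,
                                  seed = p$seed + match(f, unique(st$factor)))
    write_bed(noise[[f]], file.path(outdir, paste0("noise_", f, ".bed")),
              header = paste("matched shuffle seed",
                             metadata(noise[[f]])$seed))
  }
  write_tsv(do.call(rbind, mem_rows), file.path(outdir, "membership_counts.tsv"))
  logf("stage membership/noise: factors %s", paste(names(membership), collapse = ","))

  frag_cache <- new.env(parent = emptyenv())
  get_frags <- function(s, f) {
    key <- paste(s, f, sep = "_")
    if (!is.null(frag_cache[[key]])) return(frag_cache[[key]])
    path <- st$fragments[st$sample == s & st$factor == f]
    fs <- fragment_set(read_bed(path), sample_id = s, factor = f)
    frag_cache[[key]] <- fs
    fs
  }

  ## stage: quantify + rank-sum ordering (shared vs specific vs noise)
  ranksum_rows <- list()
  for (f in names(membership)) {
    shared <- membership_regions(membership[[f]], "shared_all")
    for (s in intersect(colnames(membership[[f]]$occupancy), st$sample)) {
      specific <- membership_regions(membership[[f]], paste0("specific:", s))
      for (track_f in unique(c(f, mark_factor))) {
        if (!any(st$sample == s & st$factor == track_f)) next
        if (length(shared) < 2 || length(specific) < 2) next
        fr <- get_frags(s, track_f)
        la <- log_region_counts(fr, shared)
        lb <- log_region_counts(fr, specific)
        ln <- log_region_counts(fr, noise[[f]])
        t1 <- rank_sum_test(la, lb); t2 <- rank_sum_test(lb, ln)
        ranksum_rows[[paste(f, s, track_f)]] <- data.frame(
          region_factor = f, sample = s, track = track_f,
          median_shared = median(la), median_specific = median(lb),
          median_noise = median(ln),
          p_shared_vs_specific = t1$p_value,
          p_specific_vs_noise = t2$p_value)
      }
    }
  }
  ranksum <- do.call(rbind, ranksum_rows); rownames(ranksum) <- NULL
  write_tsv(ranksum, file.path(outdir, "ranksum_tests.tsv"))
  logf("stage quantify: %d rank-sum contrasts", nrow(ranksum))
  if (!is.null(membership[[stratify_factor]])) {
    s1 <- colnames(membership[[stratify_factor]]$occupancy)[1]
    fr1 <- get_frags(s1, stratify_factor)
    shared1 <- membership_regions(membership[[stratify_factor]], "shared_all")
    prof <- list(
      shared = signal_matrix(fr1, shared1, genome, flank = p$flank,
                             bin_size = p$bin_size),
      noise = signal_matrix(fr1, noise[[stratify_factor]], genome,
                            flank = p$flank, bin_size = p$bin_size))
    plot_signal_profile(prof, file.path(outdir, paste0(
      "profile_", stratify_factor, "_", s1, ".svg")))
  }

  ## stage: stratify sample-specific sites by the active mark
  strata <- list(); selected_active <- list()
  if (!is.null(membership[[stratify_factor]])) {
    mem <- membership[[stratify_factor]]
    for (s in colnames(mem$occupancy)) {
      specific <- membership_regions(mem, paste0("specific:", s))
      if (length(specific) < p$k) next
      if (!any(st$sample == s & st$factor == mark_factor)) next
      sm <- signal_matrix(get_frags(s, mark_factor), specific, genome,
                          flank = p$strat_flank, bin_size = p$bin_size)
      sa <- kmeans_stratify(sm, k = p$k, seed = p$kmeans_seed,
                            n_top = p$n_top)
      strata[[s]] <- sa
      selected_active[[s]] <- specific[sa$selected]
      write_tsv(data.frame(chrom = as.character(seqnames(specific)),
                           start = bed_start(specific),
                           end = bed_end(specific),
                           cluster = sa$cluster, selected = sa$selected),
                file.path(outdir, paste0("strata_", s, ".tsv")))
      write_bed(selected_active[[s]],
                file.path(outdir, paste0("active_specific_", s, ".bed")))
    }
  }
  logf("stage stratify: k=%d n_top=%d seed=%d, %d sample(s)", p$k, p$n_top,
       p$kmeans_seed, length(strata))

  ## stage: annotate + enrich
  context <- NULL; links <- list(); enrichment <- list()
  if (!is.null(cfg$genes)) {
    ann <- read_gene_annotation(cfg$genes)
    universe <- ann$gene_id
    logf("stage annotate: universe = all %d annotated genes", length(universe))
    ctx_rows <- list()
    if (!is.null(membership[[stratify_factor]])) {
      mem <- membership[[stratify_factor]]
      for (cls in c("shared_all", paste0("specific:",
                                         colnames(mem$occupancy)))) {
        reg <- membership_regions(mem, cls)
        if (!length(reg)) next
        pct <- genomic_context(reg, ann, promoter_flank = p$promoter_flank)
        ctx_rows[[cls]] <- data.frame(class = cls, t(pct))
      }
      context <- do.call(rbind, ctx_rows); rownames(context) <- NULL
      write_tsv(context, file.path(outdir, "genomic_context.tsv"))
    }
    sets <- if (!is.null(cfg$gene_sets)) read_gmt(cfg$gene_sets) else NULL
    for (s in names(selected_active)) {
      lk <- link_regions_to_genes(selected_active[[s]], ann,
                                  window = p$window)
      links[[s]] <- lk
      write_tsv(lk$table, file.path(outdir, paste0("gene_links_", s, ".tsv")))
      if (!is.null(sets) && length(lk$genes)) {
        enr <- hypergeometric_enrichment(lk$genes, sets, universe,
                                         top_n = p$top_sets)
        enrichment[[s]] <- enr
        write_tsv(enr, file.path(outdir, paste0("enrichment_", s, ".tsv")))
      }
    }
  }

  ## stage: motifs (shared sites vs shuffled background)
  motif_table <- NULL
  if (!is.null(cfg$pwms) && !is.null(cfg$genome_fasta) &&
      !is.null(membership[[stratify_factor]])) {
    pwms <- read_jaspar(cfg$pwms)
    shared <- membership_regions(membership[[stratify_factor]], "shared_all")
    concat <- do.call(c, lapply(unname(consensus[grepl(
      paste0("_", stratify_factor, "$"), names(consensus))]), granges))
    bg <- matched_shuffle(shared, genome, exclusion = concat,
                          seed = p$seed + 101L)
    motif_table <- motif_enrichment_z(shared, bg, genome, pwms,
                                      score_fraction = p$score_fraction,
                                      top_n = p$top_motifs)
    write_tsv(motif_table, file.path(outdir, "motif_enrichment.tsv"))
    logf("stage motifs: %d PWMs, %d fg / %d bg regions", length(pwms),
         length(shared), length(bg))
  }

  ## stage: transcriptome
  sf <- NULL; de <- NULL; expr_cor <- NULL
  if (!is.null(cfg$counts)) {
    counts <- read_counts_tsv(cfg$counts)
    sf <- size_factors(counts)
    norm <- normalize_counts(counts, sf)
    loggedm <- filter_and_log(norm, floor = p$expr_floor)
    if (!is.null(cfg$group_a) && !is.null(cfg$group_b)) {
      de <- differential_expression(counts, cfg$group_a, cfg$group_b,
                                    sf = sf, fdr_max = p$de_fdr,
                                    lfc_min = p$de_lfc)
      write_tsv(de, file.path(outdir, "de_results.tsv"))
    }
    expr_cor <- correlation_matrix(loggedm)
    write_tsv(data.frame(sample = rownames(expr_cor), expr_cor),
              file.path(outdir, "correlation_expression.tsv"))
    logf("stage transcriptome: %d genes kept of %d; %d DE pass",
         nrow(loggedm), nrow(counts), if (is.null(de)) 0L else sum(de$pass))
  }

  ## stage: concordance of ChIP tracks (reads in a common region set)
  chip_cor <- NULL; chip_hc <- NULL
  if (length(membership)) {
    all_regions <- merge_intervals(
      do.call(c, unname(lapply(membership, function(m) granges(m$regions)))))
    track_keys <- names(consensus)
    cmat <- vapply(track_keys, function(key) {
      sf_ <- strsplit(key, "_")[[1]]
      log(count_fragments_in_regions(get_frags(sf_[1], sf_[2]),
                                     all_regions) + 1)
    }, numeric(length(all_regions)))
    chip_cor <- correlation_matrix(cmat)
    write_tsv(data.frame(track = rownames(chip_cor), chip_cor),
              file.path(outdir, "correlation_chip.tsv"))
    chip_hc <- hierarchical_cluster(chip_cor)
    writeLines(dendrogram_newick(chip_hc),
               file.path(outdir, "dendrogram_chip.nwk"))
    write_tsv(dendrogram_merges(chip_hc),
              file.path(outdir, "dendrogram_chip_merges.tsv"))
    logf("stage concordance: %d tracks over %d regions", ncol(cmat),
         length(all_regions))
  }

  invisible(list(qc = qc, consensus = consensus, membership = membership,
                 noise = noise, ranksum = ranksum, strata = strata,
                 selected_active = selected_active, context = context,
                 links = links, enrichment = enrichment,
                 motif_table = motif_table, size_factors = sf, de = de,
                 chip_correlation = chip_cor, chip_dendrogram = chip_hc,
                 expr_correlation = expr_cor, outdir = outdir))
}
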