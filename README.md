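# cistromics

Multi-sample cistrome concordance analysis for ChIP-seq and RNA-seq.

When several clonally related tumour samples are profiled for the same
transcription factors, the interesting questions are comparative: which
binding sites are **shared** by every sample, which are **sample-specific**,
do the specific sites sit in active chromatin or in noise, which genes do
they touch, and does any of it move the transcriptome? `cistromics`
implements that analysis as a tested, reusable R pipeline for researchers in
regulatory genomics — built around the AR/FOXA1/CTCF/H3K27ac setting of
metastatic prostate cancer, but generic over factors and samples.

The core quantities:

* **Membership decomposition.** Per factor, consensus regions are the merge
  of all samples' dual-caller peaks; region classes are *shared*
  (all samples), *specific* (exactly one) and *partial*. The shared-fraction
  summary is $n_\mathrm{shared} / (n_\mathrm{shared} + \overline{n}_\mathrm{specific})$,
  the Venn centre against the mean single-sample exclusive count.
* **Matched noise null.** Random regions matching the concatenated peaks in
  number and lengths, excluded from them — the baseline for signal
  comparisons (Wilcoxon rank-sum on log fragment counts, exact for small
  samples).
* **Active-site stratification.** Seeded k-means on the matched sample's
  H3K27ac signal matrix; the top-ranked clusters (by central signal) form
  the H3K27ac-positive "active" subset.
* **Peak-to-gene linkage and enrichment.** Nearest TSS within 20 kb of the
  site midpoint; upper-tail hypergeometric tests against GMT gene sets with
  BH correction.
* **Motif enrichment.** Log-odds PWM scanning (both strands, ≥80% of the
  maximum score) and a two-proportion z-score of hit frequency against a
  length-matched shuffled background,
  $z = (f_\mathrm{fg} - f_\mathrm{bg}) / \sqrt{f_\mathrm{bg}(1-f_\mathrm{bg})/n_\mathrm{fg}}$.
* **Differential expression.** Median-of-ratios size factors, a
  never-expressed filter (normalised count < 4 in all samples), and a
  simplified negative-binomial Wald test; genes pass at FDR ≤ 0.05 and
  |log2FC| ≥ 2.
* **Concordance.** Pearson correlation of reads-in-peaks and of expression,
  clustered with complete linkage on $d = 1 - r$.

A deterministic synthetic-study generator (`simulate_dataset()`) plants all
of this structure — shared/specific sites, an active mark, a motif, two
differential genes — so the whole pipeline is validated by parameter
recovery. See the methods vignette
(`vignettes/cistrome-concordance-methods.Rmd`) for models, parameters and
design rationale.

## Worked example

```r
library(cistromics)

ds  <- simulate_dataset(sim_config(seed = 1), "sim_study")
cfg <- config_from_dataset(ds)            # QC floor scaled to the toy study
res <- run_pipeline(cfg, "report")

mem <- res$membership$AR
length(mem$regions)                       # 872 consensus AR regions
table(mem$class)[c("shared_all", "partial")]  # 392 shared, 108 partial
round(mem$shared_fraction, 3)             # 0.808 (planted: 500/600 = 0.833)

head(res$motif_table[, c("motif_id", "f_fg", "f_bg", "z")], 3)
#>      motif_id      f_fg f_bg           z
#> 1 PLANTED_ARE 0.8035714    0 445.0540915
#> 2     DECOY_1 0.0000000    0  -0.7075582
#> 3     DECOY_2 0.0000000    0  -0.7075582

res$de[res$de$pass, c("gene_id", "base_mean", "log2fc", "fdr")]
#>     gene_id base_mean    log2fc          fdr
#> 113    G113  130.5788  3.147104 3.156408e-14
#> 140    G140  307.9081 -3.024233 2.075362e-03

truth_compare(list(membership = mem,
                   selected_active = res$selected_active,
                   motif_table = res$motif_table, de = res$de),
              ds$truth)$active_jaccard    # 0.924
```

Reading: of 872 merged consensus AR regions, 392 are occupied by all four
samples and on average ~94 are exclusive to one sample, recovering the
planted shared fraction (0.833) within 2.5 points despite 5% caller-2
dropout; the planted motif outranks all nine decoys; exactly the two planted
genes pass the differential-expression thresholds; and the H3K27ac-positive
subset of sample-specific sites is recovered with Jaccard 0.92. `report/`
holds the per-stage outputs (QC, UpSet-style membership counts, consensus
and noise BEDs, rank-sum contrasts, strata, gene links, enrichment and motif
tables, DE results, correlation matrices, dendrogram, signal profile, and a
`run_log.txt` echoing every parameter and seed).

A thin command-line wrapper is included:

```sh
Rscript scripts/run_pipeline.R --simulate sim_study --outdir report --seed 1
Rscript scripts/run_pipeline.R --config run.yaml --outdir report
```

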