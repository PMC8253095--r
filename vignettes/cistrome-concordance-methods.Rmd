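---
title: "Methods: multi-sample cistrome concordance analysis"
author: "cistromics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-sample cistrome concordance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis

`cistromics` asks a concrete question about clonally related tumour samples
profiled by ChIP-seq and RNA-seq: how much of a transcription factor's
cistrome is shared across anatomically distinct samples, are the
sample-specific binding sites genuine regulatory elements or noise, and do
the cistromic differences translate into transcriptional differences? The
package implements the full path from per-sample peak calls to that answer,
with a synthetic data generator that plants known structure so every stage
can be validated by parameter recovery.

The pipeline stages, in dependency order:

1. **Dual-caller consensus.** Peak calling is out of scope; the pipeline
   consumes two BED files per sample/factor, one from a narrow-peak caller
   and one from a second caller, and keeps the caller-1 peaks supported by at
   least 1 bp of overlap with any caller-2 peak. Caller-1 coordinates are
   retained in full, preserving peak width, rather than clipping to the
   geometric intersection.
2. **Peak-count QC.** For each factor, a sample is dropped when its consensus
   peak count falls below the Tukey lower fence `Q1 - 1.5 IQR` of the
   per-factor counts (quantiles by linear interpolation) or below an absolute
   floor (default 10 000 peaks at genome scale; the toy-study configuration
   scales the floor to 100, the fence being scale-free). On tight count
   distributions the fence is deliberately trigger-happy — with four samples
   an IQR of a few peaks can exclude a marginally lower sample — which is the
   method's nature, not a defect; every decision is reported with its reason.
3. **Membership decomposition.** Consensus regions are the gap-0 merge of all
   samples' peaks; occupancy is any-overlap. A region occupied by every
   sample is *shared*, by exactly one sample *specific*, otherwise *partial*.
   Partial regions are reported (the full UpSet-style pattern counts are
   written) but excluded from the shared-vs-specific contrasts. The
   package's *shared fraction* summary is accordingly
   `n_shared / (n_shared + mean per-sample specific count)` — the Venn
   centre against the average single-sample exclusive count — not the
   fraction over all regions including partials.
4. **Matched noise regions.** The signal null is a random region set matching
   the concatenated peak file in number and interval lengths, drawn uniformly
   over the genome (chromosome proportional to length) with rejection of any
   placement touching the exclusion set (default: the concatenation itself).
   Placed intervals may overlap one another; deduplication would distort the
   length-matched null. The seed is mandatory and echoed in the output.
5. **Signal quantification.** Fragments are counted in regions by any
   overlap, CPM-normalised (`count * 1e6 / library size`), and compared
   between region classes by a two-sided Wilcoxon rank-sum test on
   `log(count + 1)`. Binned signal matrices are centred on region midpoints
   (`floor((start + end) / 2)`), with `2 * flank / bin_size` bins of mean
   per-bp CPM coverage; out-of-chromosome bins are missing, not zero.
6. **Active-site stratification.** Sample-specific sites of the factor of
   interest are clustered by their matched sample's active-mark (H3K27ac)
   signal using Lloyd's k-means with k-means++ initialisation, 10 restarts,
   and a fixed seed (1729 by default, always logged). Clusters are ranked by
   mean signal in the central window and the top two are taken as the
   active subset.
7. **Annotation and enrichment.** Regions are classified by midpoint with
   precedence promoter > exon > intron > downstream > distal intergenic
   (promoter = TSS ± 1 kb by default); sites are linked to the gene with the
   nearest TSS within 20 kb of the site midpoint (ties keep all tied genes);
   gene lists are tested against GMT gene sets by the upper-tail
   hypergeometric distribution with Benjamini–Hochberg correction across
   sets, the universe defaulting to all annotated genes (logged). The
   essential-gene test is the same operation with a single gene set.
8. **Motif enrichment.** PWMs (JASPAR counts, pseudocount 0.01) are scanned
   over region sequences on both strands; a hit is a window scoring at least
   80% of the maximum attainable log2-odds score, and windows containing N
   are skipped. Per motif, the fraction of foreground regions with a hit is
   compared with a length-matched shuffled background via a two-proportion
   z-score, `z = (f_fg - f_bg) / sqrt(f_bg (1 - f_bg) / n_fg)` with `f_bg`
   clamped away from 0 and 1 by half a background count. This statistic is
   the package's own, chosen because it is fully specified and preserves
   enrichment *ranking* semantics; no numeric agreement with any external
   motif tool's Z score is claimed.
9. **Transcriptome.** Median-of-ratios size factors; genes whose normalised
   count is below 4 in every sample are removed ("never expressed" — the
   stricter any-sample reading is available by flag); retained values are
   `log2(x + 1)`. Two-group differential expression is a deliberately simple
   negative-binomial Wald test (below). A gene is called at
   FDR ≤ 0.05 and |log2FC| ≥ 2.
10. **Concordance.** Pearson correlation of log reads-in-peaks across all
    ChIP tracks over the union of consensus regions, and of the filtered log
    expression matrix across samples; agglomerative clustering on
    `d = 1 - r` with complete linkage, labels sorted lexicographically
    before clustering so tied merges are reproducible.

# The differential-expression model

Per gene, with normalised group means $\mu_a, \mu_b$:

$$\log_2 \mathrm{FC} = \log_2 \frac{\mu_b + 0.5}{\mu_a + 0.5}$$

The gene-wise dispersion $\alpha$ comes from the pooled within-group variance
of normalised counts by method of moments, $\alpha = (s^2 - \mu)/\mu^2$,
shrunk 50/50 toward a mean–dispersion trend $a_0 + a_1/\mu$ fitted across
genes. The Wald standard error propagates the NB variance
$\mu + \alpha \mu^2$ of each group mean through the log by the delta method;
p-values are two-sided normal, BH-adjusted. With two replicates per group the
raw method-of-moments estimate is extremely noisy; the trend shrinkage is
what keeps the test usable there. Under a null 2v2 simulation (2000 genes,
dispersion 0.05) the fraction of genes with p < 0.05 sits around 0.06 —
mildly anticonservative, which the pass rule's fold-change threshold and FDR
step absorb. This is an intentionally transparent approximation, not a
re-implementation of any published DE package; at full scale a dedicated
tool should be preferred, and the package's own test is honest about being a
calibration-checked approximation.

# The synthetic study and what it does (not) show

`simulate_dataset()` emits a complete toy study from one seed: a 3 × 1 Mb
genome, 200 genes, four samples, five factors (AR, FOXA1, CTCF, H3K27ac,
H3K27me3). Per TF factor it plants 500 core sites shared by all samples and
100 sample-specific sites per sample (log-normal widths, median 300 bp), with
core fragment intensity 3× the specific intensity over a Poisson background
(0.005 fragments/bp), 65 bp single-end reads, and a second caller emulated by
jittering caller-1 peaks ±50 bp with 5% dropout. H3K27ac is enriched at all
core sites and at the planted *active* half of every sample's AR-specific
sites — in every sample's track, encoding the observation that an enhancer
stays active whether or not the factor binds there. H3K27me3 is
coverage-only. A 15-bp androgen-response-element-like motif is planted at
core sites with probability 0.8 and specific sites with 0.3; the PWM library
holds it plus nine random decoys. Expression counts are NB (dispersion 0.05)
with exactly two genes split at |log2FC| = 3 between the two sample groups.

Choices the generator makes where realism forced a decision: planted sites
of a factor keep a ≥1 kb mutual gap, because on a 3 Mb toy genome unspaced
sites would sit inside each other's signal windows — at real genome scale
site spacing provides this for free. For the same reason the stratification
stage clusters a site-proximal ±500 bp matrix (`strat_flank`) rather than
the ±2 kb display window. And the pipeline's stratification default is k = 3
with the top 2 clusters selected: selecting a fixed number of top clusters
assumes the mark-positive population spans at most that many, so k exceeds
it by one; with k = 4 on a cleanly bimodal toy population, k-means provably
splits the active mode three ways (the background cluster contributes almost
no within-cluster variance) and a top-2 rule must miss a third of the active
sites. `kmeans_stratify()` itself defaults to k = 4 for data where the
active population is more heterogeneous.

What passing recovery tests shows: the region algebra, membership
decomposition, null construction, stratification, linkage, enrichment, motif
ranking and DE calling are internally consistent and recover planted
structure under realistic noise (caller disagreement, Poisson background,
NB counts). What it does not show: robustness to copy-number-driven
coverage, GC and mappability bias, fragment-length effects, read-level
error, or caller-specific artefacts — none of which the generator models.
Numbers from the deposited patient data (tens of thousands of sites,
specific-site counts in the 50k–80k range) are not reproducible at this
scale and are not claimed.

# Numerical conventions and degenerate inputs

* Coordinates are BED 0-based half-open everywhere at the interface;
  book-ended intervals share zero bases (never overlap) but have separation
  0 and therefore merge at gap 0, conserving covered bp.
* Chromosome names match as exact strings; `validate_chroms()` reports
  names absent from the genome instead of aliasing.
* The rank-sum test enumerates all assignments exactly when
  `n_a * n_b <= 64` (valid under ties); otherwise a normal approximation
  with tie and continuity corrections. All values tied across both samples
  gives p = 1 with a degeneracy flag.
* Zero-variance columns yield missing correlations, never 0; clustering
  refuses missing entries rather than guessing.
* Empty peak sets, empty queries, all-zero genes and genome-covering
  exclusions raise informative errors or well-defined empties, exercised in
  the test suite.
* Problem sizes in the shipped tests: the default synthetic study
  (3 Mb genome, ~2 700 planted sites, ~600 k fragments) for end-to-end
  recovery, and a 2 × 0.4 Mb study for unit-level pipeline checks — chosen
  so a complete validation run stays in the minutes range on one core.

# Known limitations

* The motif z-score is a ranking statistic, not a calibrated p-value.
* The DE test's normal Wald approximation is mildly anticonservative at
  n = 2 per group (see calibration above).
* The QC fence assumes peak counts of the same factor are comparable across
  samples; batch effects between samples would confound it.
* `run_pipeline()` recomputes all stages on each call; with fixed seeds the
  rerun is byte-deterministic, which substitutes for stage caching at these
  problem sizes.
* Full-scale replication against deposited patient data requires the
  original raw data and legacy tool versions and is outside the package's
  desk-scale scope.
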