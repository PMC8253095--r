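toy_ann <- function() {
  data.frame(gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
             start = c(10000L, 40000L), end = c(20000L, 45000L),
             strand = c("+", "-"),
             tss = c(10000L, 44999L), stringsAsFactors = FALSE)
}

test_that("genomic_context classifies midpoints with precedence", {
  empty_ann <- toy_ann()[0, ]
  pct <- genomic_context(gintervals("chr1", 100, 200), empty_ann)
  expect_equal(unname(pct["distal_intergenic"]), 100)

  on_tss <- genomic_context(gintervals("chr1", 9950, 10050), toy_ann())
  expect_equal(unname(on_tss["promoter"]), 100)

  three <- gintervals(rep("chr1", 3), c(9950, 15000, 70000),
                      c(10050, 15200, 70100))
  pct3 <- genomic_context(three, toy_ann())
  expect_equal(sum(pct3), 100, tolerance = 1e-9)
  expect_equal(unname(pct3[c("promoter", "intron", "distal_intergenic")]),
               rep(100 / 3, 3))
  expect_error(genomic_context(GRanges(), toy_ann()), "empty")
})

test_that("exon precedence over intron when exons are provided", {
  exons <- gintervals("chr1", 14950, 15250)
  pct <- genomic_context(gintervals("chr1", 15000, 15200), toy_ann(),
                         exons = exons)
  expect_equal(unname(pct["exon"]), 100)
})

test_that("link_regions_to_genes takes the nearest TSS within the window", {
  ann <- data.frame(gene_id = c("near", "far"), chrom = "chr1",
                    start = c(110000L, 130000L), end = c(112000L, 132000L),
                    strand = "+", tss = c(110000L, 130000L),
                    stringsAsFactors = FALSE)
  lk <- link_regions_to_genes(gintervals("chr1", 99950, 100050), ann,
                              window = 20000)
  expect_equal(lk$genes, "near")

  solo <- ann[2, ]; solo$tss <- 125000L
  lk2 <- link_regions_to_genes(gintervals("chr1", 99950, 100050), solo,
                               window = 20000)
  expect_length(lk2$genes, 0)
  expect_equal(formals(link_regions_to_genes)$window, 20000L)

  tie <- data.frame(gene_id = c("left", "right"), chrom = "chr1",
                    start = c(95000L, 105000L), end = c(96000L, 106000L),
                    strand = "+", tss = c(95000L, 105000L),
                    stringsAsFactors = FALSE)
  lk3 <- link_regions_to_genes(gintervals("chr1", 99950, 100050), tie,
                               window = 20000)
  expect_setequal(lk3$genes, c("left", "right"))
})

test_that("a genome-wide window assigns every region with a same-chrom gene", {
  withr::with_seed(51, regions <- random_intervals(30, c(chr1 = 10000L)))
  ann <- toy_ann(); ann$chrom <- "chr1"
  lk <- link_regions_to_genes(regions, ann, window = 1e9)
  expect_equal(sort(unique(lk$table$region_index)), seq_along(regions))
})

test_that("hypergeometric p matches the closed form and enumeration", {
  universe <- paste0("g", 1:10)
  sets <- list(S = universe[1:5])
  res <- hypergeometric_enrichment(universe[1:4], sets, universe, top_n = 5)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)  # C(5,4)*C(5,0)/C(10,4)

  # exhaustive enumeration oracle over all C(N, n) draws, N <= 12
  withr::with_seed(57, {
    for (rep in 1:5) {
      N <- sample(6:12, 1)
      uni <- paste0("u", seq_len(N))
      K <- sample(2:(N - 1), 1)
      n <- sample(2:(N - 1), 1)
      set <- list(X = uni[seq_len(K)])
      query <- sample(uni, n)
      k_obs <- length(intersect(query, set$X))
      draws <- combn(N, n)
      k_all <- colSums(draws <= K)
      expect_equal(
        hypergeometric_enrichment(query, set, uni, top_n = 1)$p_value,
        mean(k_all >= k_obs), tolerance = 1e-12)
    }
  })
})

test_that("enrichment results respect BH ordering and universe filtering", {
  universe <- paste0("g", 1:50)
  withr::with_seed(61, sets <- lapply(setNames(1:6, paste0("S", 1:6)),
                                      function(i) sample(universe, 12)))
  query <- sets$S1[1:10]
  res <- hypergeometric_enrichment(query, sets, universe, top_n = 6)
  full <- attr(res, "all")
  expect_true(all(diff(full$fdr) >= -1e-12))
  expect_true(all(full$fdr >= full$p_value - 1e-12))
  expect_equal(full$set_name[1], "S1")
  expect_warning(
    hypergeometric_enrichment(c(query, "absent"), sets, universe, top_n = 3),
    "outside the universe")
  expect_error(hypergeometric_enrichment(query, sets, character(0)), "universe")
})

test_that("read_gmt parses sets and rejects malformed lines", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("SET1\tdesc\tg1\tg2\tg3", "SET2\tdesc\tg9"), path)
  sets <- read_gmt(path)
  expect_equal(sets$SET1, c("g1", "g2", "g3"))
  writeLines("BAD\tonly_desc", path)
  expect_error(read_gmt(path), "line 1")
})
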