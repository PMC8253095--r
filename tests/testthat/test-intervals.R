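test_that("read_bed parses records, skips comments, flags sortedness", {
  p <- write_tmp_bed(c("# a comment", "track name=x", "chr1\t0\t100"))
  gr <- read_bed(p)
  expect_length(gr, 1)
  expect_equal(as.character(seqnames(gr)), "chr1")
  expect_equal(bed_start(gr), 0L)
  expect_equal(bed_end(gr), 100L)
  expect_true(metadata(gr)$sorted)

  empty <- read_bed(write_tmp_bed(character(0)))
  expect_length(empty, 0)

  unsorted <- read_bed(write_tmp_bed(c("chr1\t500\t600", "chr1\t0\t100",
                                       "chr2\t10\t20")))
  expect_length(unsorted, 3)
  expect_false(metadata(unsorted)$sorted)
})

test_that("read_bed errors name the offending line", {
  p <- write_tmp_bed(c("chr1\t0\t100", "chr1\tfoo\t200"))
  expect_error(read_bed(p), "line 2")
  p2 <- write_tmp_bed(c("chr1\t300\t200"))
  expect_error(read_bed(p2), "line 1")
  p3 <- write_tmp_bed(c("chr1\t100"))
  expect_error(read_bed(p3), "line 1")
})

test_that("write_bed/read_bed round-trips coordinates bit-exactly", {
  withr::with_seed(7, {
    gr <- random_intervals(50)
    mcols(gr)$name <- sprintf("r%02d", seq_along(gr))
    mcols(gr)$score <- sample.int(1000, 50)
  })
  path <- tempfile(fileext = ".bed")
  write_bed(gr, path)
  back <- read_bed(path)
  expect_identical(bed_start(back), bed_start(gr))
  expect_identical(bed_end(back), bed_end(gr))
  expect_identical(as.character(seqnames(back)), as.character(seqnames(gr)))
  expect_identical(as.character(mcols(back)$name), mcols(gr)$name)
})

test_that("merge_intervals unions by gap and conserves covered bp at gap 0", {
  s <- gintervals(c("chr1", "chr1"), c(0, 50), c(100, 150))
  m <- merge_intervals(s, gap = 0)
  expect_equal(bed_start(m), 0L)
  expect_equal(bed_end(m), 150L)

  disjoint <- gintervals(c("chr1", "chr1"), c(0, 200), c(100, 300))
  expect_equal(covered_bp(merge_intervals(disjoint)), covered_bp(disjoint))
  expect_length(merge_intervals(disjoint), 2)

  gapped <- gintervals(c("chr1", "chr1"), c(0, 110), c(100, 200))
  expect_length(merge_intervals(gapped, gap = 10), 1)
  expect_equal(bed_end(merge_intervals(gapped, gap = 10)), 200L)
  # book-ended intervals have separation 0 and merge at gap 0; covered bp
  # is conserved either way
  abut <- gintervals(c("chr1", "chr1"), c(0, 100), c(100, 200))
  expect_length(merge_intervals(abut, gap = 0), 1)
  expect_equal(covered_bp(merge_intervals(abut, gap = 0)), covered_bp(abut))
})

test_that("merge_intervals is idempotent and conserves bp on random sets", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      s <- random_intervals(sample.int(80, 1))
      m1 <- merge_intervals(s)
      m2 <- merge_intervals(m1)
      expect_identical(granges(m1), granges(m2))
      expect_equal(covered_bp(s), covered_bp(m1))
    }
  })
})

test_that("overlap_query matches examples and is symmetric in content", {
  a <- gintervals("chr1", 0, 10)
  b <- gintervals("chr1", 5, 15)
  expect_equal(overlap_query(a, b), data.frame(query = 1L, subject = 1L))
  # half-open abutment: zero shared bases
  expect_equal(nrow(overlap_query(gintervals("chr1", 0, 10),
                                  gintervals("chr1", 10, 20))), 0)
  d <- gintervals(rep("chr1", 3), c(0, 100, 200), c(10, 110, 210))
  expect_equal(overlap_query(d, d),
               data.frame(query = 1:3, subject = 1:3))
})

test_that("overlap_query equals brute force on random sets", {
  withr::with_seed(23, {
    for (rep in 1:8) {
      a <- random_intervals(sample.int(100, 1))
      b <- random_intervals(sample.int(100, 1))
      min_bp <- sample.int(5, 1)
      got <- overlap_query(a, b, min_bp = min_bp)
      want <- brute_force_overlaps(a, b, min_bp = min_bp)
      o1 <- got[order(got$query, got$subject), ]
      o2 <- want[order(want$query, want$subject), ]
      expect_equal(unname(as.matrix(o1)), unname(as.matrix(o2)))
      # content-symmetry under argument swap
      swapped <- overlap_query(b, a, min_bp = min_bp)
      expect_setequal(paste(got$query, got$subject),
                      paste(swapped$subject, swapped$query))
    }
  })
})

test_that("genome loading validates sizes and chromosome names", {
  cs <- tempfile()
  writeLines(c("chr1\t10000", "chr2\t8000"), cs)
  g <- load_genome(chrom_sizes = cs)
  expect_equal(g$sizes, c(chr1 = 10000L, chr2 = 8000L))
  gr <- gintervals(c("chr1", "chrX"), c(0, 0), c(10, 10))
  expect_equal(validate_chroms(gr, g), "chrX")
  bad <- tempfile()
  writeLines(c("chr1\t0"), bad)
  expect_error(read_chrom_sizes(bad), "> 0")
})

test_that("gene annotation readers extract strand-aware TSS", {
  bed <- write_tmp_bed(c("chr1\t1000\t5000\tgeneA\t0\t+",
                         "chr1\t8000\t9000\tgeneB\t0\t-"))
  ann <- read_gene_annotation(bed)
  expect_equal(ann$tss, c(1000L, 8999L))
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(paste("chr1", "src", "gene", "1001", "5000", ".", "+", ".",
                     'gene_id "geneA";', sep = "\t"),
               paste("chr1", "src", "gene", "8001", "9000", ".", "-", ".",
                     'gene_id "geneB";', sep = "\t")), gtf)
  ann2 <- read_gene_annotation(gtf)
  expect_equal(ann2$tss, ann$tss)
  expect_equal(ann2$gene_id, ann$gene_id)
})
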