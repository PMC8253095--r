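test_that("fragment counting is any-overlap with half-open semantics", {
  frags <- gintervals(c("chr1", "chr1"), c(0, 100), c(65, 165))
  regions <- gintervals("chr1", 50, 150)
  expect_equal(count_fragments_in_regions(frags, regions), 2L)
  expect_equal(count_fragments_in_regions(GRanges(), regions), 0L)
  # fragment abutting the region end is not counted
  expect_equal(count_fragments_in_regions(gintervals("chr1", 150, 215),
                                          regions), 0L)
  # a fragment spanning two regions increments both
  two <- gintervals(c("chr1", "chr1"), c(0, 60), c(50, 100))
  expect_equal(count_fragments_in_regions(gintervals("chr1", 40, 70), two),
               c(1L, 1L))
})

test_that("counts over disjoint regions never exceed the library size", {
  g <- toy_genome()
  withr::with_seed(3, {
    frags <- random_intervals(300, g$sizes, max_width = 65)
    regions <- merge_intervals(random_intervals(40, g$sizes))
  })
  fs <- fragment_set(frags)
  expect_lte(sum(count_fragments_in_regions(fs, regions)), fs$library_size)
})

test_that("cpm_normalize scales by library size", {
  expect_equal(cpm_normalize(5, 1e6), 5)
  expect_equal(cpm_normalize(4, 2e6), 2)
  expect_equal(cpm_normalize(c(0, 0), 1e6), c(0, 0))
  m <- matrix(c(2, 4, 10, 20), nrow = 2)
  got <- cpm_normalize(m, c(1e6, 2e6))
  expect_equal(got, matrix(c(2, 4, 5, 10), nrow = 2))
  expect_error(cpm_normalize(1, 0), "> 0")
})

test_that("signal_matrix bins coverage around region midpoints", {
  g <- toy_genome(c(chr1 = 100000L))
  # one fragment everywhere: per-bp coverage 1 -> all bins equal
  starts <- seq(0L, 100000L - 65L, by = 65L)
  flat <- gintervals(rep("chr1", length(starts)), starts, starts + 65L)
  region <- gintervals("chr1", 50000, 50400)
  m <- signal_matrix(flat, region, g, flank = 2000, bin_size = 25,
                     library_size = 1e6)
  expect_equal(ncol(m), 160)
  expect_equal(unname(m[1, ]), rep(1, 160))
  # near-edge region: out-of-window bins missing, row kept
  edge <- gintervals("chr1", 100, 300)
  me <- signal_matrix(flat, edge, g, flank = 2000, bin_size = 25,
                      library_size = 1e6)
  expect_true(anyNA(me[1, ]))
  expect_false(all(is.na(me[1, ])))
  expect_error(signal_matrix(flat, region, g, flank = 2000, bin_size = 30),
               "divisible")
})

test_that("signal_matrix display order sorts rows by total signal", {
  g <- toy_genome(c(chr1 = 50000L))
  withr::with_seed(9, {
    hot0 <- floor(runif(200, 10000, 10200))
    frags <- gintervals(rep("chr1", 200), hot0, hot0 + 65)
  })
  regions <- gintervals(c("chr1", "chr1"), c(30000, 10000), c(30400, 10400))
  m <- signal_matrix(frags, regions, g, flank = 500, bin_size = 25)
  expect_equal(attr(m, "display_order"), c(2L, 1L))
})

test_that("rank_sum_test matches enumeration and handles degeneracy", {
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.1)  # 2 of C(6,3)=20 assignments as extreme

  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1)

  tied <- rank_sum_test(rep(2, 5), rep(2, 7))
  expect_equal(tied$p_value, 1)
  expect_true(tied$degenerate)

  withr::with_seed(21, {
    a <- rnorm(200); b <- rnorm(200, 3)
  })
  expect_lt(rank_sum_test(a, b)$p_value, 0.005)
})

test_that("exact rank-sum p agrees with the wilcox.test oracle without ties", {
  withr::with_seed(33, {
    for (rep in 1:10) {
      na <- sample(2:8, 1); nb <- sample(2:8, 1)
      a <- rnorm(na); b <- rnorm(nb)
      ours <- rank_sum_test(a, b)
      ref <- wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
      expect_equal(unname(ours$statistic), unname(ref$statistic))
    }
  })
})

test_that("normal approximation tracks the exact test for moderate n", {
  withr::with_seed(37, {
    for (rep in 1:10) {
      na <- sample(9:20, 1); nb <- sample(9:20, 1)  # n_a * n_b > 64
      a <- rnorm(na); b <- rnorm(nb, 0.5)
      approx <- rank_sum_test(a, b)
      ref <- wilcox.test(a, b, exact = TRUE)
      # spec band: approximate p within 0.02 of exact for these sizes
      expect_lt(abs(approx$p_value - ref$p.value), 0.02)
      expect_equal(approx$method, "normal-approximation")
    }
  })
})
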