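test_that("size_factors reproduces median-of-ratios on toy matrices", {
  counts <- matrix(c(10, 20, 20, 40), nrow = 2, byrow = FALSE,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- size_factors(counts)
  expect_equal(unname(sf[2] / sf[1]), 2)
  norm <- normalize_counts(counts, sf)
  expect_equal(norm[, 1], norm[, 2])

  same <- matrix(rep(c(5, 8, 11), 3), ncol = 3,
                 dimnames = list(NULL, paste0("s", 1:3)))
  expect_equal(unname(size_factors(same)), rep(1, 3))

  # scaling one library by c scales its factor by c relative to the others
  scaled <- counts; scaled[, 2] <- scaled[, 2] * 3
  sf0 <- size_factors(counts); sf3 <- size_factors(scaled)
  expect_equal(unname((sf3[2] / sf3[1]) / (sf0[2] / sf0[1])), 3)
})

test_that("size_factors agrees with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  withr::with_seed(83, {
    counts <- matrix(rnbinom(400 * 4, mu = 80, size = 10), ncol = 4,
                     dimnames = list(paste0("g", 1:400), paste0("s", 1:4)))
  })
  ours <- size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("size_factors errors without an all-nonzero gene unless told otherwise", {
  counts <- matrix(c(0, 5, 5, 0), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(counts), "pseudo_reference")
  sf <- size_factors(counts, pseudo_reference = TRUE)
  expect_true(all(sf > 0))
})

test_that("filter_and_log drops never-expressed genes and logs the rest", {
  norm <- rbind(low = c(3, 3, 3, 3), burst = c(0, 5, 0, 0),
                seven = c(7, 7, 7, 7))
  out <- filter_and_log(norm, floor = 4)
  expect_setequal(rownames(out), c("burst", "seven"))
  expect_equal(unname(out["seven", 1]), 3)  # log2(7 + 1)
  strict <- filter_and_log(norm, floor = 4, mode = "any")
  expect_equal(rownames(strict), "seven")
})

test_that("differential expression recovers planted genes exactly", {
  withr::with_seed(89, {
    n <- 5000
    base <- rlnorm(n, log(100), 1)
    mu <- matrix(base, nrow = n, ncol = 4)
    planted <- c(101L, 202L)
    mu[planted[1], 3:4] <- base[planted[1]] * 8   # log2FC = +3
    mu[planted[2], 3:4] <- base[planted[2]] / 8   # log2FC = -3
    counts <- matrix(rnbinom(n * 4, mu = mu, size = 1 / 0.01), nrow = n,
                     dimnames = list(paste0("g", 1:n), paste0("s", 1:4)))
  })
  de <- differential_expression(counts, c("s1", "s2"), c("s3", "s4"))
  expect_setequal(de$gene_id[de$pass], paste0("g", c(101, 202)))
  expect_equal(sign(de$log2fc[de$gene_id == "g101"]), 1)
  expect_equal(sign(de$log2fc[de$gene_id == "g202"]), -1)
  expect_true(all(abs(de$log2fc[de$pass]) >= 2))
  expect_true(all(de$fdr[de$pass] <= 0.05))
})

test_that("equal group means give near-zero fold change and large p", {
  counts <- matrix(c(100, 100, 100, 100,
                     50, 50, 50, 50), nrow = 2, byrow = TRUE,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  de <- differential_expression(counts, c("s1", "s2"), c("s3", "s4"))
  expect_equal(de$log2fc, c(0, 0))
  expect_true(all(de$p_value > 0.9))
  # all-zero genes are excluded from testing
  counts0 <- rbind(counts, g3 = 0)
  expect_equal(nrow(differential_expression(counts0, c("s1", "s2"),
                                            c("s3", "s4"))), 2)
})

test_that("the Wald test is roughly calibrated under the null", {
  withr::with_seed(97, {
    n <- 2000
    base <- rlnorm(n, log(100), 1)
    counts <- matrix(rnbinom(n * 4, mu = rep(base, 4), size = 1 / 0.05),
                     nrow = n,
                     dimnames = list(paste0("g", 1:n), paste0("s", 1:4)))
  })
  de <- differential_expression(counts, c("s1", "s2"), c("s3", "s4"))
  frac <- mean(de$p_value < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.08)
})

test_that("count tables round-trip through TSV", {
  counts <- matrix(1:12, nrow = 3,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = rownames(counts), counts),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_counts_tsv(path), counts)
})
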