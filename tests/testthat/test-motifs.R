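consensus_pwm <- function(s, id = "CONS") {
  bases <- strsplit(s, "")[[1]]
  mat <- matrix(0, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) mat[bases[j], j] <- 1
  pwm_from_counts(mat, id = id, pseudocount = 0.01)
}

test_that("read_jaspar normalises counts into probability matrices", {
  path <- tempfile(fileext = ".jaspar")
  writeLines(c(">M1 test",
               "A [ 10 0 0 ]", "C [ 0 10 0 ]",
               "G [ 0 0 10 ]", "T [ 0 0 0 ]"), path)
  pwms <- read_jaspar(path)
  expect_named(pwms, "M1")
  expect_equal(colSums(pwms$M1$mat), rep(1, 3), tolerance = 1e-9)
  expect_true(all(pwms$M1$mat > 0))  # pseudocount applied
  expect_equal(unname(which.max(pwms$M1$mat[, 2])), 2)  # C dominates
})

test_that("scan_pwm finds a planted consensus exactly once", {
  pwm <- consensus_pwm("ACGTAC")
  withr::with_seed(71, {
    bg <- paste(sample(c("A", "C"), 60, replace = TRUE), collapse = "")
  })
  seqn <- paste0(substr(bg, 1, 20), "ACGTAC", substr(bg, 21, 60))
  hits <- scan_pwm(seqn, pwm, score_fraction = 0.9)
  expect_equal(hits$forward, 21L)
  # reverse-complement planted instance is found on the reverse strand
  rc_seq <- paste0(substr(bg, 1, 20), "GTACGT", substr(bg, 21, 60))
  hits_rc <- scan_pwm(rc_seq, pwm, score_fraction = 0.9)
  expect_equal(hits_rc$reverse, 21L)
})

test_that("uniform PWM yields no hits under the positive-score guard", {
  mat <- matrix(1, nrow = 4, ncol = 5,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pwm_from_counts(mat, id = "UNIF")
  hits <- scan_pwm("ACGTACGTACGT", pwm, score_fraction = 0.5)
  expect_length(hits$forward, 0)
  expect_length(hits$reverse, 0)
  expect_lte(hits$max_score, 0)
})

test_that("palindromic PWM hits coincide on both strands", {
  pwm <- consensus_pwm("ACGCGT")  # reverse complement of ACGCGT is itself
  seqn <- "TTTTACGCGTTTTTACGCGTTTT"
  hits <- scan_pwm(seqn, pwm, score_fraction = 0.95)
  expect_equal(hits$forward, hits$reverse)
  expect_length(hits$forward, 2)
})

test_that("windows containing N are skipped", {
  pwm <- consensus_pwm("ACGT")
  hits <- scan_pwm("ACNTACGT", pwm, score_fraction = 0.9)
  expect_equal(hits$forward, 5L)
})

test_that("scan_pwm agrees with a brute-force per-offset scorer", {
  withr::with_seed(73, {
    for (rep in 1:5) {
      L <- sample(4:8, 1)
      cnt <- matrix(runif(4 * L, 0, 20), nrow = 4,
                    dimnames = list(c("A", "C", "G", "T"), NULL))
      pwm <- pwm_from_counts(cnt, id = "R")
      seqn <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                    collapse = "")
      frac <- runif(1, 0.6, 0.95)
      got <- scan_pwm(seqn, pwm, score_fraction = frac)
      # independent scorer: substring loop with direct probability lookup
      score1 <- function(s, p) {
        b <- strsplit(s, "")[[1]]
        sum(vapply(seq_along(b),
                   function(j) log2(p$mat[b[j], j] / 0.25), numeric(1)))
      }
      maxsc <- sum(apply(log2(pwm$mat / 0.25), 2, max))
      rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seqn, "")[[1]]),
                                         collapse = ""))
      fwd <- which(vapply(1:(200 - L + 1), function(i)
        score1(substr(seqn, i, i + L - 1), pwm) >= frac * maxsc, logical(1)))
      rev_rc <- which(vapply(1:(200 - L + 1), function(i)
        score1(substr(rc, i, i + L - 1), pwm) >= frac * maxsc, logical(1)))
      rev <- sort(200 - L - rev_rc + 2)
      expect_equal(got$forward, fwd)
      expect_equal(got$reverse, rev)
    }
  })
})

test_that("motif z-score matches the two-proportion formula on planted data", {
  motif <- "AGAACAGCATGTTCT"
  pwm <- consensus_pwm(motif, id = "ARE")
  withr::with_seed(79, {
    chars <- sample(c("A", "C", "G", "T"), 6000, replace = TRUE)
    plant_at <- function(region) 30 * (region - 1) + 6  # 0-based offset
    for (r in 1:50) {  # fg regions 1..100, first 50 carry the motif
      p0 <- plant_at(r)
      chars[(p0 + 1):(p0 + 15)] <- strsplit(motif, "")[[1]]
    }
    for (r in 101:110) {  # bg regions 101..200, 10 carry the motif
      p0 <- plant_at(r)
      chars[(p0 + 1):(p0 + 15)] <- strsplit(motif, "")[[1]]
    }
  })
  genome <- structure(list(
    sizes = c(chr1 = 6000L),
    seq = Biostrings::DNAStringSet(c(chr1 = paste(chars, collapse = "")))),
    class = "Genome")
  starts <- 30 * (0:199)
  fg <- gintervals(rep("chr1", 100), starts[1:100], starts[1:100] + 30)
  bg <- gintervals(rep("chr1", 100), starts[101:200], starts[101:200] + 30)
  res <- motif_enrichment_z(fg, bg, genome, list(ARE = pwm),
                            score_fraction = 0.9)
  expect_equal(res$f_fg, 0.5)
  expect_equal(res$f_bg, 0.1)
  expect_equal(res$z, 0.4 / sqrt(0.1 * 0.9 / 100), tolerance = 1e-9)
  # degenerate equality: f_fg = f_bg gives z = 0
  res0 <- motif_enrichment_z(fg, fg, genome, list(ARE = pwm),
                             score_fraction = 0.9)
  expect_equal(res0$z, 0)
})
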