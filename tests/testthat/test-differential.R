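test_that("z-score matches its closed form in both modes", {
  expect_equal(zScore(4, 1, absoluteDenominator = FALSE), 3 / sqrt(5))
  expect_equal(zScore(7, 7, FALSE), 0)
  expect_equal(zScore(-1, 1, TRUE), -2 / sqrt(2))
  expect_equal(zScore(0, 0, TRUE), 0)  # silent genes score 0
  expect_error(zScore(-1, 1, absoluteDenominator = FALSE), "non-negative")
})

test_that("z-score is antisymmetric and sqrt-scale covariant", {
  set.seed(3)
  m <- rnorm(50, 5, 3); w <- rnorm(50, 5, 3)
  for (abs_mode in c(TRUE, FALSE)) {
    mm <- if (abs_mode) m else abs(m)
    ww <- if (abs_mode) w else abs(w)
    expect_equal(zScore(mm, ww, abs_mode), -zScore(ww, mm, abs_mode))
    for (k in c(0.5, 4)) {
      expect_equal(zScore(k * mm, k * ww, abs_mode),
                   sqrt(k) * zScore(mm, ww, abs_mode))
    }
  }
})

test_that("the equal-variance t-test matches the t distribution and degenerate rules", {
  r <- tTestTwoSample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(r$statistic), 3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(r$p.value, 2 * pt(-3 / sqrt(2 / 3), df = 4), tolerance = 1e-10)
  same <- tTestTwoSample(c(1, 2), c(1, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  zv <- tTestTwoSample(c(1, 1), c(2, 2))  # zero pooled variance, unequal means
  expect_equal(zv$p.value, 0)
  expect_equal(tTestTwoSample(c(3, 3), c(3, 3))$p.value, 1)
  expect_error(tTestTwoSample(1, c(2, 3)), "at least 2")
})

test_that("differential calls use strict thresholds on averaged replicates", {
  # construct genes with known means; noise-free replicates make p degenerate
  mut <- matrix(c(9, 9, 9, 4, 4, 4, 2.25, 2.25, 2.25), 3, byrow = TRUE,
                dimnames = list(c("up", "edge", "down"), NULL))
  wt <- matrix(c(4, 4, 4, 1, 1, 1, 9, 9, 9), 3, byrow = TRUE,
               dimnames = list(c("up", "edge", "down"), NULL))
  # z(up) = 5/sqrt(13) ~ 1.387 < 1.5; use thresholds that isolate strictness
  res <- callDifferential(mut, wt, zThresh = 1.0, pThresh = 0.05)
  expect_equal(as.character(res[res$gene_id == "up", "call"]), "up")
  expect_equal(as.character(res[res$gene_id == "down", "call"]), "down")
  # z(edge) = 3/sqrt(5) ~ 1.3416: calling with zThresh exactly there must be ns
  res2 <- callDifferential(mut, wt, zThresh = 3 / sqrt(5), pThresh = 0.05)
  expect_equal(as.character(res2[res2$gene_id == "edge", "call"]), "ns")
  # mismatched gene universes are rejected
  expect_error(callDifferential(mut, wt[1:2, ]), "same genes")
})

test_that("overlap of differential sets partitions the called genes", {
  mk <- function(genes, call) {
    data.frame(gene_id = c(genes, "zz"), modality = "rna",
               mutant_mean = 1, wt_mean = 1, z = 2, p = 0.01,
               call = factor(c(rep(call, length(genes)), "ns"),
                             levels = c("up", "down", "ns")))
  }
  ov <- overlapSets(mk(c("g1", "g2"), "up"), mk(c("g2", "g3"), "up"), "up")
  expect_equal(ov, list(only_a = "g1", shared = "g2", only_b = "g3"))
  same <- mk(c("g1", "g2"), "up")
  ov2 <- overlapSets(same, same, "up")
  expect_length(ov2$only_a, 0)
  expect_length(ov2$only_b, 0)
  ov3 <- overlapSets(mk("g1", "up"), mk("g9", "up"), "up")
  expect_length(ov3$shared, 0)
})

test_that("box statistics use Tukey hinges, 1.5 IQR whiskers and 1.58 notches", {
  bs <- boxStats(1:9)
  expect_equal(bs$median, 5)
  expect_equal(c(bs$hinge_lo, bs$hinge_hi), c(3, 7))
  expect_equal(bs$iqr, 4)
  expect_equal(c(bs$notch_lo, bs$notch_hi), 5 + c(-1, 1) * 1.58 * 4 / 3)
  const <- boxStats(rep(2.5, 6))
  expect_true(all(unlist(const[-1]) == 2.5 | unlist(const[-1]) == 0))
  one <- boxStats(42)
  expect_equal(c(one$median, one$whisker_lo, one$whisker_hi,
                 one$notch_lo, one$notch_hi), rep(42, 5))
  expect_error(boxStats(numeric()), "at least one")
})

test_that("box statistics agree with a direct sort-based implementation", {
  set.seed(13)
  for (i in 1:300) {
    n <- sample(1:60, 1)
    x <- switch(sample(3, 1), rnorm(n), rpois(n, 4) + 0.5,
                sample(c(-5, 0, 5), n, replace = TRUE))
    got <- boxStats(x)
    want <- box_oracle(x)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
  }
})

test_that("promoter-set shift compares subset and global distributions", {
  z <- setNames(c(rnorm(200, 0, 0.2), rnorm(20, -3, 0.2)),
                sprintf("g%03d", 1:220))
  shifted <- promoterSetShift(z, sprintf("g%03d", 201:220))
  expect_true(shifted$shift)
  expect_lt(shifted$subset$median, shifted$global$notch_lo)
  all_genes <- promoterSetShift(z, names(z))
  expect_equal(all_genes$global, all_genes$subset)
  expect_false(all_genes$shift)
  expect_error(promoterSetShift(z, character()), "empty")
  expect_error(promoterSetShift(z, "nope"), "subset")
})

test_that("mark integration classifies sign patterns exhaustively", {
  me3 <- c(a = -2, b = -1, c = 0.5, d = 0, e = -2)
  ac <- c(a = 1.5, b = -0.5, c = 2, d = 0, e = 1)
  rna <- c(a = 2, b = 0.5, c = -1, d = 0, e = -1)
  got <- integrateMarks(me3, ac, rna)
  expect_equal(as.character(got),
               c("derepressed_activated", "me3_loss_only", "ac_gain_only",
                 "unchanged", "other"))
  # exhaustive and exclusive over random inputs
  set.seed(21)
  z <- function() setNames(rnorm(100), sprintf("g%d", 1:100))
  cats <- integrateMarks(z(), z(), z(), eps = 0.5)
  expect_false(any(is.na(cats)))
  expect_error(integrateMarks(me3, ac[1:3], rna), "universe")
})
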