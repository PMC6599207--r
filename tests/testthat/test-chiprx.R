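test_that("PCR duplicates collapse to one read per coordinate key", {
  reads <- make_reads(rep("chr1", 3), c(100, 100, 100), c(150, 150, 150),
                      strand = c("+", "+", "-"))
  dd <- dedupReads(reads)
  expect_equal(dd$n_raw, 3)
  expect_equal(dd$n_dedup, 2)  # opposite strands are distinct molecules
  expect_equal(as.character(strand(dd$reads)), c("+", "-"))
  # strand can be dropped from the key
  expect_equal(dedupReads(reads, ignoreStrand = TRUE)$n_dedup, 1)
  empty <- dedupReads(reads[0])
  expect_equal(empty$n_raw, 0)
  expect_length(empty$reads, 0)
})

test_that("the MAPQ filter is strict and extension is 3-prime with clipping", {
  reads <- make_reads(rep("chr1", 3), c(100, 100, 100), c(150, 150, 150),
                      strand = c("+", "-", "+"), mapq = c(60, 60, 5))
  ext <- filterAndExtend(reads)
  expect_length(ext, 2)                      # mapq 5 removed (strictly > 5)
  expect_length(filterAndExtend(make_reads("chr1", 100, 150, mapq = 6)), 1)
  # + read [100,150) -> [100,400); - read [100,150) -> [0,150) after clipping
  expect_equal(start(ext) - 1, c(100, 0))
  expect_equal(end(ext), c(400, 150))
  rs <- filterAndExtend(reads[1:2], mode = "resize")
  # fixed total length anchored at the 5' end; the minus-strand read would
  # reach position -100 and is clipped at the chromosome start
  expect_equal(width(rs), c(250, 150))
  expect_equal(start(rs)[1] - 1, 100)
  expect_equal(end(rs)[2], 150)
})

test_that("window counts use >= 1 bp overlap on half-open windows", {
  pw <- promoterWindows(c("gA", "gB"), "chr1", c(5000, 6000), c("+", "+"))
  # windows gA [3500,6500), gB [4500,7500): overlapping windows both count
  reads <- make_reads(rep("chr1", 3), c(3400, 0, 5000), c(3700, 3500, 5050))
  n <- windowCounts(reads, pw)
  expect_equal(unname(n["gA"]), 2)  # 1-bp overlap counts; [0,3500) does not
  expect_equal(unname(n["gB"]), 1)  # the shared read counts in each window
  expect_equal(length(windowCounts(reads, pw[0])), 0)
})

test_that("Rx normalization is spike-denominated RPKM with exact arithmetic", {
  st <- libraryStats("L1", 3e6, 2e6, 1.5e6, 5e5, 1e6)
  expect_equal(rxNormalize(30, 3000, st), 10)
  expect_equal(rxNormalize(0, 3000, st), 0)
  # doubling the spike count exactly halves the signal
  expect_equal(rxNormalize(30, 3000, 2e6), 5)
  st0 <- libraryStats("empty", 10, 10, 10, 10, 0)
  expect_error(rxNormalize(1, 3000, st0), "empty")
})

test_that("Rx signal is invariant under joint read-count scaling", {
  # scaling target and spike-in together must not move the Rx value --
  # this is what distinguishes spike-in from library-size normalization
  for (k in c(2, 5, 10)) {
    expect_equal(rxNormalize(30 * k, 3000, 1e6 * k), rxNormalize(30, 3000, 1e6))
  }
})

test_that("input subtraction preserves negative net signal", {
  chip <- data.frame(gene_id = c("g1", "g2", "g3"), rx_signal = c(10, 2, 7))
  inp <- data.frame(gene_id = c("g3", "g2", "g1"), rx_signal = c(0, 5, 4))
  net <- subtractInput(chip, inp)$net_signal
  expect_equal(net, c(6, -3, 7))  # no flooring; input 0 leaves chip unchanged
  expect_error(subtractInput(chip, inp[1:2, ]), "same genes")
})

test_that("replicate averaging is the arithmetic mean and labels the result", {
  rec <- data.frame(gene_id = rep(c("g1", "g2"), 2), mark = "K27me3",
                    condition = "WT", replicate = rep(c("rep1", "rep2"), each = 2),
                    raw_count = c(1, 2, 3, 4), rx_signal = c(5, 1, 9, 3),
                    net_signal = c(6, -2, 8, 2))
  av <- averageReplicates(rec)
  expect_equal(av$net_signal[av$gene_id == "g1"], 7)
  expect_equal(av$net_signal[av$gene_id == "g2"], 0)
  expect_equal(unique(av$replicate), "averaged")
  single <- averageReplicates(rec[rec$replicate == "rep1", ])
  expect_equal(single$net_signal, rec$net_signal[1:2])
  rec2 <- rec; rec2$condition[1] <- "MUT"
  expect_error(averageReplicates(rec2), "mixed")
})

test_that("library accounting inequalities hold through the full chain", {
  sim <- simulateChipRx(simulationConfig(seed = 5, n_genes = 40,
                                         reads_per_library = 20000))
  q <- quantifyLibrary(sim$libraries[["WT.K27me3.rep1"]], sim$promoters,
                       "K27me3", "WT")
  st <- q$stats
  expect_true(st@n_raw >= st@n_dedup)
  expect_true(st@n_dedup >= st@n_pass_mq)
  expect_equal(st@n_pass_mq, st@n_target + st@n_spike)
  expect_true(all(q$signal$raw_count >= 0))
  expect_true(validObject(st))
})

test_that("the composed pipeline is deterministic and recovers global loss", {
  cfg <- simulationConfig(seed = 9, n_genes = 120, reads_per_library = 60000)
  sim <- simulateChipRx(cfg, c("WT", "K27M"))
  run <- function() {
    lapply(c("WT", "K27M"), function(cond) {
      chipRxPromoterSignal(
        sim$libraries[paste(cond, "K27me3", c("rep1", "rep2"), sep = ".")],
        sim$libraries[[paste(cond, "K27me3", "input", sep = ".")]],
        sim$promoters, "K27me3", cond)$signal
    })
  }
  a <- run(); b <- run()
  expect_identical(a, b)  # fixed input -> identical output
  wt <- setNames(a[[1]]$net_signal, a[[1]]$gene_id)
  mut <- setNames(a[[2]]$net_signal, a[[2]]$gene_id)
  not_planted <- setdiff(names(wt), sim$truth$planted_up)
  ratio <- median(mut[not_planted] / wt[not_planted])
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.65)
})
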