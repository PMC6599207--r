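test_that("generators are pure functions of config and seed", {
  cfg <- simulationConfig(seed = 42, n_genes = 30, reads_per_library = 5000)
  a <- simulateCohort(cfg); b <- simulateCohort(cfg)
  expect_identical(a, b)
  ca <- simulateChipRx(cfg); cb <- simulateChipRx(cfg)
  expect_identical(ca, cb)
  ea <- simulateExpression(cfg); eb <- simulateExpression(cfg)
  expect_identical(ea, eb)
  ga <- simulateEngraftment(cfg); gb <- simulateEngraftment(cfg)
  expect_identical(ga, gb)
  # a different seed perturbs the stochastic layers
  expect_false(identical(simulateCohort(simulationConfig(seed = 43))$variants,
                         simulateCohort(simulationConfig(seed = 42))$variants))
})

test_that("cohort structure matches the configured fractions", {
  co <- simulateCohort(simulationConfig(seed = 1))
  expect_equal(nrow(co$samples), 434)
  expect_equal(sum(co$samples$diagnosis == "s_aml"), 33)  # round(434 * 0.076)
  expect_equal(sum(!is.na(co$samples$h3_mutation)), 7)
  mut <- co$samples[!is.na(co$samples$h3_mutation), ]
  expect_equal(sum(mut$diagnosis == "s_aml"), 3)  # round(7 * 3/7)
  expect_equal(nrow(co$variants), 7)
  expect_true(all(co$variants$vaf == co$variants$alt_reads / co$variants$depth))
  # no mutants -> empty variant table, full sample sheet
  none <- simulateCohort(simulationConfig(seed = 1, n_h3_mutant = 0))
  expect_equal(nrow(none$variants), 0)
  expect_equal(nrow(none$samples), 434)
})

test_that("configuration validity rejects inconsistent study designs", {
  expect_error(simulationConfig(frac_up = 0.6), "frac_up")
  expect_error(simulationConfig(saml_frac = 1.5), "saml_frac")
  expect_error(simulationConfig(n_h3_mutant = 100, mutant_saml_frac = 1,
                                n_samples = 434, saml_frac = 0.076),
               "s_aml|s-AML|mutant")
  expect_error(simulationConfig(me3_global_loss = 0), "me3_global_loss")
  expect_error(simulationConfig(engraft_group_means = c(1, 2)), "named")
  # NA mutant placement fraction is the unstructured-null mode, not an error
  expect_s4_class(simulationConfig(mutant_saml_frac = NA_real_),
                  "SimulationConfig")
})

test_that("spike-in read share is condition-independent and near spike_frac", {
  cfg <- simulationConfig(seed = 8, n_genes = 25, reads_per_library = 20000)
  sim <- simulateChipRx(cfg)
  n3 <- 3 * sqrt(20000 * 0.02 * 0.98)
  for (lib in sim$libraries) {
    sp <- sum(lib$species == "spikein" & !duplicated(lib))
    expect_gt(sp, 20000 * 0.02 - n3)
    expect_lt(sp, 20000 * 0.02 + n3)
  }
  det <- simulateChipRx(simulationConfig(seed = 8, n_genes = 25,
                                         reads_per_library = 20000,
                                         deterministic = TRUE))
  for (lib in det$libraries)
    expect_equal(sum(lib$species == "spikein"), round(20000 * 0.02))
})

test_that("planted gene sets have the configured size and sit atop the mark", {
  cfg <- simulationConfig(seed = 4, n_genes = 200, reads_per_library = 5000)
  sim <- simulateChipRx(cfg)
  expect_length(sim$truth$planted_up, 20)   # 200 * frac_up 0.1
  expect_length(sim$truth$planted_down, 20)
  expect_length(intersect(sim$truth$planted_up, sim$truth$planted_down), 0)
  # planted up-genes carry above-median repressive mark in WT
  med <- median(sim$truth$lambda_me3)
  expect_true(all(sim$truth$lambda_me3[sim$truth$planted_up] > med))
  # and the extra loss factor applies only to them
  expect_equal(unname(unique(sim$truth$me3_loss_by_gene[sim$truth$planted_up])),
               0.5 * 0.5)
  others <- setdiff(names(sim$truth$me3_loss_by_gene), sim$truth$planted_up)
  expect_equal(unname(unique(sim$truth$me3_loss_by_gene[others])), 0.5)
})

test_that("engraftment draws stay inside [0, 100] and degenerate to the means", {
  eng <- simulateEngraftment(simulationConfig(seed = 6, engraft_sd = 40,
                                              n_mice_per_group = 50))
  expect_true(all(eng$records$percent_engraftment >= 0))
  expect_true(all(eng$records$percent_engraftment <= 100))
  flat <- simulateEngraftment(simulationConfig(seed = 6, engraft_sd = 0))
  by_g <- vapply(split(flat$records$percent_engraftment, flat$records$group),
                 unique, 0)
  expect_equal(unname(by_g[c("WT", "MUT")]), c(0.63, 29.8))
})

test_that("a null configuration gives mutant and wild-type the same law", {
  # with no global loss, no extra planted loss and no acetylation gain, the
  # mutant K27me3 libraries are generated from the identical intensity vector
  cfg <- simulationConfig(seed = 15, n_genes = 60, reads_per_library = 30000,
                          me3_global_loss = 1, me3_planted_extra_loss = 1,
                          ac_gain = 1)
  sim <- simulateChipRx(cfg)
  sig <- lapply(c("WT", "K27M"), function(cond)
    chipRxPromoterSignal(
      sim$libraries[paste(cond, "K27me3", c("rep1", "rep2"), sep = ".")],
      sim$libraries[[paste(cond, "K27me3", "input", sep = ".")]],
      sim$promoters, "K27me3", cond)$signal)
  ratio <- median(sig[[2]]$net_signal / sig[[1]]$net_signal)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.25)
})

test_that("a written study round-trips through the package readers", {
  dir <- withr::local_tempdir()
  cfg <- simulationConfig(seed = 2, n_samples = 40, n_h3_mutant = 3,
                          saml_frac = 0.2, mutant_saml_frac = 1 / 3,
                          n_genes = 10, reads_per_library = 2000)
  writeSimulatedStudy(cfg, dir)
  sheet <- readSampleSheet(file.path(dir, "samples.tsv"))
  expect_equal(nrow(sheet), 40)
  vars <- readVariantTable(file.path(dir, "variants.tsv"), "targeted")
  expect_equal(nrow(vars), 3)
  reads <- readBedReads(file.path(dir, "WT.K27me3.rep1.bed"))
  expect_equal(length(reads),
               length(simulateChipRx(cfg)$libraries[["WT.K27me3.rep1"]]))
  ex <- readExpressionTable(file.path(dir, "expression.tsv"))
  expect_equal(dim(ex), c(10, 6))
  eng <- readEngraftmentTable(file.path(dir, "engraftment.tsv"))
  expect_equal(nrow(eng), 12)
})
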