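## Seeded generators for cohorts, ChIP-Rx read sets, expression tables and
## engraftment tables with the statistical structure the pipeline assumes.
## Every generator is a pure function of its SimulationConfig (seed
## included); `deterministic = TRUE` replaces all sampling by expectations.

.GENE_SPACING <- 10000   # bp between simulated TSSs; windows never abut
.READ_LEN <- 50          # single-end read length (bp)
.BG_FRAC <- 0.3          # share of non-spike reads that are background
.SPIKE_CHROM <- "dmel_2L"
.SPIKE_CHROM_LEN <- 1e6
.LOW_MQ_FRAC <- 0.05     # reads with mapq <= 5, removed by the MQ filter
.DUP_FRAC <- 0.03        # PCR duplicate rate

## Shared gene universe: per-gene ChIP intensities, expression baseline and
## the planted up/down sets. Planted up-genes are taken from the top of the
## H3K27me3 intensity distribution (their promoters carry above-median
## repressive mark in WT), the planted down set from the next ranks.
.simUniverse <- function(config) {
  n <- as.integer(config@n_genes)
  gene_id <- sprintf("g%04d", seq_len(n))
  tss <- 5000 + (seq_len(n) - 1) * .GENE_SPACING  # 0-based
  strand <- rep(c("+", "-"), length.out = n)
  if (config@deterministic) {
    q <- qnorm((seq_len(n) - 0.5) / n)
    lambda_me3 <- exp(log(5) + q)
    lambda_ac <- exp(log(5) + rev(q))
    base_expr <- exp(log(8) + q[order(seq_len(n) %% 7)])  # fixed scramble
  } else {
    set.seed(config@seed + 101L)
    lambda_me3 <- rlnorm(n, log(5), 1)
    lambda_ac <- rlnorm(n, log(5), 1)
    base_expr <- rlnorm(n, log(8), 1)
  }
  n_up <- round(n * config@frac_up)
  ord <- order(lambda_me3, decreasing = TRUE)
  planted_up <- gene_id[ord[seq_len(n_up)]]
  planted_down <- gene_id[ord[n_up + seq_len(n_up)]]
  list(gene_id = gene_id, chrom = "chr1", tss = tss, strand = strand,
       chrom_len = n * .GENE_SPACING + .GENE_SPACING,
       lambda_me3 = setNames(lambda_me3, gene_id),
       lambda_ac = setNames(lambda_ac, gene_id),
       base_expr = setNames(base_expr, gene_id),
       planted_up = planted_up, planted_down = planted_down,
       promoters = promoterWindows(gene_id, "chr1", tss, strand))
}

#' Promoter windows of the simulated gene universe
#' @param config a \code{\link{simulationConfig}}.
#' @return GRanges of 3 kb TSS-centered windows.
#' @export
simulatedPromoters <- function(config) .simUniverse(config)$promoters

#' Simulate an AML cohort with rare H3-mutant samples
#'
#' Generates \code{round(n_samples * saml_frac)} secondary-AML samples among
#' \code{n_samples}, plants \code{n_h3_mutant} H3 mutations of which
#' \code{round(n_h3_mutant * mutant_saml_frac)} fall in s-AML samples, and
#' emits one targeted variant call per mutant with true VAF drawn uniformly
#' in [0.40, 0.55] and alternate reads ~ Binomial(depth, VAF) at
#' Poisson(depth_mean) coverage.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with \code{samples} (cohort sheet data.frame),
#'   \code{variants} (targeted variant calls) and \code{truth}
#'   (sample_id, true_vaf).
#' @export
simulateCohort <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  n <- as.integer(config@n_samples)
  n_saml <- round(n * config@saml_frac)
  n_mut <- as.integer(config@n_h3_mutant)
  det <- config@deterministic
  if (!det) set.seed(config@seed + 1L)
  idx_saml <- if (det) seq_len(n_saml) else sort(sample(n, n_saml))
  is_saml <- seq_len(n) %in% idx_saml
  idx_other <- setdiff(seq_len(n), idx_saml)
  if (is.na(config@mutant_saml_frac)) {
    ## null structure: mutants land uniformly, ignoring diagnosis
    mut_idx <- if (det) seq_len(n_mut) else sample(n, n_mut)
  } else {
    n_mut_saml <- round(n_mut * config@mutant_saml_frac)
    mut_idx <- c(
      if (n_mut_saml > 0) { if (det) idx_saml[seq_len(n_mut_saml)]
                            else sample(idx_saml, n_mut_saml) },
      if (n_mut - n_mut_saml > 0) { if (det) idx_other[seq_len(n_mut - n_mut_saml)]
                                    else sample(idx_other, n_mut - n_mut_saml) })
  }
  lesions <- rep(c("HIST1H3F K27I", "HIST1H3H K27M", "H3F3A K27M",
                   "HIST1H3A Q69H", "H3F3A A26P", "H3F3C R2Q", "H3F3C R8H"),
                 length.out = max(n_mut, 1))
  sample_id <- sprintf("P%04d", seq_len(n))
  h3 <- rep(NA_character_, n)
  if (n_mut > 0) h3[mut_idx] <- lesions[seq_len(n_mut)]
  samples <- data.frame(
    sample_id = sample_id,
    diagnosis = factor(ifelse(is_saml, "s_aml", "de_novo_aml"),
                       levels = .diagnosis_levels),
    cohort = rep(c("cohort1", "cohort2"), length.out = n),
    h3_mutation = h3,
    k27_mutant = !is.na(h3) & grepl("K27", h3),
    paired_with = NA_character_,
    unpaired = FALSE,
    stringsAsFactors = FALSE
  )
  if (n_mut == 0) {
    variants <- data.frame(sample_id = character(), gene = character(),
                           protein_change = character(), chrom = character(),
                           pos = integer(), ref = character(), alt = character(),
                           alt_reads = numeric(), depth = numeric(),
                           vaf = numeric(), callers = character(),
                           assay = character(), stringsAsFactors = FALSE)
    truth <- data.frame(sample_id = character(), true_vaf = numeric())
    return(list(samples = samples, variants = variants, truth = truth))
  }
  true_vaf <- if (det) rep(0.475, n_mut) else runif(n_mut, 0.40, 0.55)
  depth <- if (det) rep(config@depth_mean, n_mut) else
    rpois(n_mut, config@depth_mean)
  depth <- pmax(depth, 1)
  alt <- if (det) round(depth * true_vaf) else rbinom(n_mut, depth, true_vaf)
  gene <- vapply(strsplit(lesions[seq_len(n_mut)], " "), `[`, "", 1)
  prot <- vapply(strsplit(lesions[seq_len(n_mut)], " "), `[`, "", 2)
  variants <- data.frame(
    sample_id = sample_id[mut_idx], gene = gene, protein_change = prot,
    chrom = "chr6", pos = 26000000L + seq_len(n_mut),
    ref = "A", alt = "T", alt_reads = alt, depth = depth,
    vaf = alt / depth, callers = "", assay = "targeted",
    stringsAsFactors = FALSE
  )
  list(samples = samples, variants = variants,
       truth = data.frame(sample_id = sample_id[mut_idx], true_vaf = true_vaf,
                          stringsAsFactors = FALSE))
}

.sim_mapq <- function(n, det) {
  if (det || n == 0) return(rep(60L, n))
  low <- runif(n) < .LOW_MQ_FRAC
  ifelse(low, as.integer(floor(runif(n, 0, 6))), 60L)
}

.sim_strand <- function(n, det) {
  if (det || n == 0) return(rep("+", n))
  sample(c("+", "-"), n, replace = TRUE)
}

## Build one library's GRanges from promoter read counts + background + spike.
.sim_library <- function(universe, counts, n_bg, n_spike, det) {
  tss <- setNames(universe$tss, universe$gene_id)
  gidx <- rep(seq_along(counts), counts)
  n_prom <- length(gidx)
  prom_start <- if (det) {
    offs <- unlist(lapply(counts[counts > 0], function(k)
      round(seq(-1500, 1450 - .READ_LEN, length.out = k))), use.names = FALSE)
    tss[gidx] + offs
  } else {
    tss[gidx] + floor(runif(n_prom, -1500, 1450 - .READ_LEN))
  }
  bg_start <- if (det) {
    round(seq(0, universe$chrom_len - .READ_LEN, length.out = max(n_bg, 1)))[seq_len(n_bg)]
  } else floor(runif(n_bg, 0, universe$chrom_len - .READ_LEN))
  sp_start <- if (det) {
    round(seq(0, .SPIKE_CHROM_LEN - .READ_LEN, length.out = max(n_spike, 1)))[seq_len(n_spike)]
  } else floor(runif(n_spike, 0, .SPIKE_CHROM_LEN - .READ_LEN))
  start0 <- pmax(0, c(prom_start, bg_start, sp_start))
  chrom <- c(rep(universe$chrom, n_prom + n_bg), rep(.SPIKE_CHROM, n_spike))
  n_tot <- length(start0)
  gr <- GRanges(chrom, IRanges(start0 + 1, width = .READ_LEN),
                strand = .sim_strand(n_tot, det),
                name = sprintf("r%d", seq_len(n_tot)),
                mapq = .sim_mapq(n_tot, det),
                species = factor(ifelse(chrom == .SPIKE_CHROM, "spikein",
                                        "target"),
                                 levels = c("target", "spikein")))
  if (!det && n_tot > 0) {
    n_dup <- round(.DUP_FRAC * n_tot)
    if (n_dup > 0) gr <- c(gr, gr[sample(n_tot, n_dup, replace = TRUE)])
  }
  gr
}

#' Simulate spike-in ChIP (ChIP-Rx) read libraries
#'
#' For each condition ("WT" plus at least one mutant label), each mark
#' (H3K27me3, H3K27ac), two ChIP technical replicates and one input library
#' are generated as 50 bp single-end reads. Spike-in reads are
#' Binomial(reads_per_library, spike_frac) on the spike chromosome in every
#' library — the spike-in chromatin share is condition-independent, which is
#' the premise that lets Rx normalization expose global signal change.
#' Promoter reads per gene are Poisson with intensity proportional to the
#' gene's mark intensity, multiplied in mutant H3K27me3 libraries by
#' \code{me3_global_loss} (and additionally by \code{me3_planted_extra_loss}
#' at planted up-genes), and in mutant H3K27ac libraries by \code{ac_gain}
#' at planted up-genes. A global loss therefore shrinks the mutant target
#' library rather than redistributing a fixed read total. Input libraries
#' contain uniform background only (plus spike-in), at the same normalized
#' background density as the ChIP libraries, so that input subtraction
#' removes exactly the non-specific component.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param conditions condition labels; must contain "WT" and at least one
#'   mutant label.
#' @return list with \code{libraries} (named list
#'   \code{<condition>.<mark>.<rep|input>} of GRanges), \code{promoters}
#'   and \code{truth} (planted sets, per-gene intensities, loss factors).
#' @export
simulateChipRx <- function(config, conditions = c("WT", "K27M")) {
  stopifnot(is(config, "SimulationConfig"))
  if (!"WT" %in% conditions || length(conditions) < 2)
    stop("config error: conditions must contain \"WT\" and at least one mutant label",
         call. = FALSE)
  if (anyDuplicated(conditions))
    stop("config error: duplicate condition labels", call. = FALSE)
  universe <- .simUniverse(config)
  det <- config@deterministic
  if (!det) set.seed(config@seed + 2L)
  N <- config@reads_per_library
  libraries <- list()
  loss_by_gene <- setNames(rep(config@me3_global_loss, length(universe$gene_id)),
                           universe$gene_id)
  loss_by_gene[universe$planted_up] <-
    loss_by_gene[universe$planted_up] * config@me3_planted_extra_loss
  for (cond in conditions) {
    mutant <- cond != "WT"
    for (mark in .mark_levels) {
      lambda <- if (mark == "K27me3") universe$lambda_me3 else universe$lambda_ac
      w <- lambda
      if (mutant && mark == "K27me3") w <- lambda * loss_by_gene
      if (mutant && mark == "K27ac")
        w[universe$planted_up] <- w[universe$planted_up] * config@ac_gain
      for (rep_lab in c("rep1", "rep2", "input")) {
        n_spike <- if (det) round(N * config@spike_frac) else
          rbinom(1, N, config@spike_frac)
        n_nonspike <- N - n_spike
        if (rep_lab == "input") {
          ## input carries the same non-specific background density (in Rx
          ## units) as the ChIP libraries, so subtraction removes exactly
          ## the non-specific component
          counts <- setNames(rep(0L, length(lambda)), names(lambda))
          n_bg <- round(n_nonspike * .BG_FRAC)
        } else {
          n_bg <- round(n_nonspike * .BG_FRAC)
          budget <- n_nonspike - n_bg
          mu <- budget * w / sum(lambda)
          counts <- if (det) round(mu) else rpois(length(mu), mu)
          counts <- setNames(counts, names(lambda))
        }
        libraries[[paste(cond, mark, rep_lab, sep = ".")]] <-
          .sim_library(universe, counts, n_bg, n_spike, det)
      }
    }
  }
  list(libraries = libraries, promoters = universe$promoters,
       truth = list(planted_up = universe$planted_up,
                    planted_down = universe$planted_down,
                    lambda_me3 = universe$lambda_me3,
                    lambda_ac = universe$lambda_ac,
                    me3_loss_by_gene = loss_by_gene,
                    ac_gain = config@ac_gain))
}

#' Simulate a replicate expression (RPKM) table
#'
#' Baseline RPKM is log-normal over the shared gene universe; planted
#' up-genes are multiplied by \code{expr_effect} in the mutant condition and
#' the disjoint planted down set divided by it. Each replicate adds
#' truncated-normal multiplicative noise with coefficient of variation
#' \code{expr_cv}.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param conditions two condition labels, reference ("WT") first.
#' @return list with \code{rpkm} (matrix gene x condition_replicate),
#'   \code{truth} (planted_up, planted_down, base RPKM).
#' @export
simulateExpression <- function(config, conditions = c("WT", "MUT")) {
  stopifnot(is(config, "SimulationConfig"))
  if (length(conditions) != 2 || conditions[1] != "WT")
    stop("config error: conditions must be c(\"WT\", <mutant label>)",
         call. = FALSE)
  universe <- .simUniverse(config)
  det <- config@deterministic
  if (!det) set.seed(config@seed + 3L)
  base <- universe$base_expr
  mut_base <- base
  mut_base[universe$planted_up] <- mut_base[universe$planted_up] * config@expr_effect
  mut_base[universe$planted_down] <- mut_base[universe$planted_down] / config@expr_effect
  k <- as.integer(config@n_replicates)
  cols <- c(sprintf("%s_rep%d", conditions[1], seq_len(k)),
            sprintf("%s_rep%d", conditions[2], seq_len(k)))
  m <- matrix(NA_real_, nrow = length(base), ncol = 2 * k,
              dimnames = list(universe$gene_id, cols))
  for (j in seq_len(k)) {
    noise <- function(mu) if (det) mu else
      pmax(0, mu * (1 + rnorm(length(mu), 0, config@expr_cv)))
    m[, j] <- noise(base)
    m[, k + j] <- noise(mut_base)
  }
  list(rpkm = m,
       truth = list(planted_up = universe$planted_up,
                    planted_down = universe$planted_down,
                    base_rpkm = base))
}

#' Simulate a two-group engraftment table
#'
#' Per group, percent engraftment values are drawn from a Normal
#' (group mean, engraft_sd) truncated to [0, 100] by inverse-CDF sampling.
#'
#' @param config a \code{\link{simulationConfig}}; groups come from
#'   \code{names(engraft_group_means)}.
#' @return list with \code{records} (mouse_id, group, percent_engraftment)
#'   and \code{truth} (group means and sd).
#' @export
simulateEngraftment <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  det <- config@deterministic
  if (!det) set.seed(config@seed + 4L)
  n <- as.integer(config@n_mice_per_group)
  sd <- config@engraft_sd
  recs <- do.call(rbind, lapply(names(config@engraft_group_means), function(g) {
    mu <- config@engraft_group_means[[g]]
    x <- if (det || sd <= 0) rep(mu, n) else {
      plo <- pnorm(0, mu, sd); phi <- pnorm(100, mu, sd)
      qnorm(runif(n, plo, phi), mu, sd)
    }
    data.frame(mouse_id = sprintf("%s_m%d", g, seq_len(n)), group = g,
               percent_engraftment = pmin(100, pmax(0, x)),
               stringsAsFactors = FALSE)
  }))
  rownames(recs) <- NULL
  list(records = recs,
       truth = data.frame(group = names(config@engraft_group_means),
                          mean = unname(config@engraft_group_means),
                          sd = sd))
}

#' Write a complete simulated study to disk
#'
#' Emits every generated table in the package's external formats, together
#' with planted-truth files, so downstream stages can be run file-to-file.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param dir output directory (created if needed).
#' @param conditions ChIP/expression condition labels.
#' @return invisibly, the vector of files written.
#' @export
writeSimulatedStudy <- function(config, dir, conditions = c("WT", "K27M")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, paste0(...))
  written <- character()
  co <- simulateCohort(config)
  writeSampleSheet(co$samples, p("samples.tsv"))
  writeVariantTable(co$variants, p("variants.tsv"))
  .write_tsv(co$truth, p("truth_cohort.tsv"))
  chip <- simulateChipRx(config, conditions)
  writePromoters(chip$promoters, p("promoters.tsv"))
  for (lib in names(chip$libraries))
    writeBedReads(chip$libraries[[lib]], p(lib, ".bed"))
  .write_tsv(data.frame(gene_id = names(chip$truth$lambda_me3),
                        lambda_me3 = unname(chip$truth$lambda_me3),
                        lambda_ac = unname(chip$truth$lambda_ac),
                        me3_loss = unname(chip$truth$me3_loss_by_gene),
                        planted_up = names(chip$truth$lambda_me3) %in%
                          chip$truth$planted_up,
                        planted_down = names(chip$truth$lambda_me3) %in%
                          chip$truth$planted_down),
             p("truth_genes.tsv"))
  expr <- simulateExpression(config, c("WT", setdiff(conditions, "WT")[1]))
  writeExpressionTable(expr$rpkm, p("expression.tsv"))
  eng <- simulateEngraftment(config)
  writeEngraftmentTable(eng$records, p("engraftment.tsv"))
  .write_tsv(eng$truth, p("truth_engraftment.tsv"))
  invisible(list.files(dir, full.names = TRUE))
}
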