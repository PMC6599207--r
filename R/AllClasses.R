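## Central S4 parameter and bookkeeping classes.

.diagnosis_levels <- c("de_novo_aml", "s_aml", "remission", "other")
.mark_levels <- c("K27me3", "K27ac")

#' Screening thresholds for variant retention and clonality classification
#'
#' Holds the retention rules applied to targeted (amplicon) and exome variant
#' calls, and the VAF thresholds used to classify a variant as belonging to
#' the major leukemic clone or as detectable in a remission sample.
#'
#' @slot targeted_min_vaf minimum variant allele frequency for targeted calls.
#' @slot targeted_min_alt minimum number of alternate-supporting reads.
#' @slot exome_min_callers minimum number of callers agreeing on an exome call.
#' @slot exome_min_support minimum supporting-read fraction for exome calls.
#' @slot blacklist data.frame with columns chrom, pos, ref, alt of sites to
#'   drop (a stand-in for common-polymorphism databases, supplied as a file).
#' @slot major_clone_min_vaf diagnosis VAF at or above which a variant is
#'   assigned to the major clone.
#' @slot detect_min_vaf VAF at or above which a variant counts as detected in
#'   a remission sample.
#' @export
setClass("ScreenConfig", representation(
  targeted_min_vaf = "numeric",
  targeted_min_alt = "numeric",
  exome_min_callers = "numeric",
  exome_min_support = "numeric",
  blacklist = "data.frame",
  major_clone_min_vaf = "numeric",
  detect_min_vaf = "numeric"
))

setValidity("ScreenConfig", function(object) {
  fr <- c(
    targeted_min_vaf = object@targeted_min_vaf,
    exome_min_support = object@exome_min_support,
    major_clone_min_vaf = object@major_clone_min_vaf,
    detect_min_vaf = object@detect_min_vaf
  )
  bad <- names(fr)[fr < 0 | fr > 1 | is.na(fr)]
  if (length(bad))
    return(sprintf("fraction slots out of [0,1]: %s", paste(bad, collapse = ", ")))
  if (object@targeted_min_alt < 0) return("targeted_min_alt must be >= 0")
  if (object@exome_min_callers < 1) return("exome_min_callers must be >= 1")
  need <- c("chrom", "pos", "ref", "alt")
  if (nrow(object@blacklist) && !all(need %in% names(object@blacklist)))
    return("blacklist must have columns chrom, pos, ref, alt")
  TRUE
})

#' Construct a ScreenConfig
#'
#' Defaults follow the study's retention rules: targeted calls kept at
#' VAF >= 10\% with >= 20 alternate reads; exome calls kept when called by at
#' least two of three callers with >= 20\% supporting reads.
#'
#' @param targeted_min_vaf,targeted_min_alt targeted-assay retention rules.
#' @param exome_min_callers,exome_min_support exome consensus rules.
#' @param blacklist data.frame of (chrom, pos, ref, alt) sites to exclude.
#' @param major_clone_min_vaf,detect_min_vaf clonality thresholds.
#' @return A validated \linkS4class{ScreenConfig}.
#' @examples
#' screenConfig()
#' @export
screenConfig <- function(targeted_min_vaf = 0.10, targeted_min_alt = 20,
                         exome_min_callers = 2, exome_min_support = 0.20,
                         blacklist = data.frame(chrom = character(),
                                                pos = integer(),
                                                ref = character(),
                                                alt = character()),
                         major_clone_min_vaf = 0.35, detect_min_vaf = 0.10) {
  new("ScreenConfig",
      targeted_min_vaf = targeted_min_vaf, targeted_min_alt = targeted_min_alt,
      exome_min_callers = exome_min_callers, exome_min_support = exome_min_support,
      blacklist = blacklist,
      major_clone_min_vaf = major_clone_min_vaf, detect_min_vaf = detect_min_vaf)
}

setMethod("show", "ScreenConfig", function(object) {
  cat("ScreenConfig\n")
  cat(sprintf("  targeted: VAF >= %.3f, alt reads >= %d\n",
              object@targeted_min_vaf, as.integer(object@targeted_min_alt)))
  cat(sprintf("  exome:    >= %d callers, support >= %.3f\n",
              as.integer(object@exome_min_callers), object@exome_min_support))
  cat(sprintf("  clonality: major clone VAF >= %.2f, remission detect VAF >= %.2f\n",
              object@major_clone_min_vaf, object@detect_min_vaf))
  cat(sprintf("  blacklist: %d site(s)\n", nrow(object@blacklist)))
})

#' Simulation parameters for the synthetic cohort / ChIP-Rx / expression /
#' engraftment generators
#'
#' One object defines an entire simulated study; every generator is a pure
#' function of it (including the seed). Defaults emulate the study
#' conditions: a 434-sample two-site cohort with 7.6\% secondary AML, seven
#' H3-mutant samples (three of them s-AML) at heterozygous-range VAFs
#' (0.40-0.55) and deep targeted coverage; ChIP libraries with 2\% spike-in
#' chromatin, 50 bp single-end reads, two technical replicates, a two-fold
#' global H3K27me3 depletion in mutant cells with extra loss at planted
#' up-genes, promoter H3K27ac gain at those genes; triplicate RNA abundance
#' with planted four-fold up/down genes; and two engraftment groups of six
#' mice whose means match the secondary-transplant summaries.
#'
#' @slot seed integer seed; identical configs give byte-identical output.
#' @slot n_samples,saml_frac cohort size and secondary-AML fraction.
#' @slot n_h3_mutant,mutant_saml_frac number of H3-mutant samples and the
#'   fraction of them assigned to s-AML (NA places mutants uniformly at
#'   random across diagnoses — the unstructured null).
#' @slot depth_mean mean targeted sequencing depth at the variant site.
#' @slot n_genes,frac_up gene universe size and planted up-regulated fraction
#'   (an equally sized disjoint down set is also planted; hence frac_up <= 0.5).
#' @slot me3_global_loss mutant/WT ratio of promoter H3K27me3 (< 1 = loss).
#' @slot me3_planted_extra_loss additional multiplicative loss applied at
#'   planted up-genes in mutant H3K27me3 libraries.
#' @slot ac_gain H3K27ac fold-gain at planted up-genes in mutant libraries.
#' @slot spike_frac fraction of each library's reads that are spike-in.
#' @slot reads_per_library nominal reads per WT library.
#' @slot expr_effect,expr_cv planted expression fold-change and replicate CV.
#' @slot n_replicates RNA replicates per condition.
#' @slot engraft_group_means named numeric, percent engraftment per group.
#' @slot engraft_sd,n_mice_per_group engraftment noise SD (percent) and
#'   group size.
#' @slot deterministic replace all sampling by expectations (exact unit tests).
#' @export
setClass("SimulationConfig", representation(
  seed = "integer",
  n_samples = "numeric", saml_frac = "numeric",
  n_h3_mutant = "numeric", mutant_saml_frac = "numeric",
  depth_mean = "numeric",
  n_genes = "numeric", frac_up = "numeric",
  me3_global_loss = "numeric", me3_planted_extra_loss = "numeric",
  ac_gain = "numeric",
  spike_frac = "numeric", reads_per_library = "numeric",
  expr_effect = "numeric", expr_cv = "numeric", n_replicates = "numeric",
  engraft_group_means = "numeric", engraft_sd = "numeric",
  n_mice_per_group = "numeric",
  deterministic = "logical"
))

setValidity("SimulationConfig", function(object) {
  fr <- c(saml_frac = object@saml_frac, frac_up = object@frac_up,
          spike_frac = object@spike_frac, expr_cv = object@expr_cv)
  ## mutant_saml_frac may be NA: mutants then land uniformly at random
  if (!is.na(object@mutant_saml_frac))
    fr <- c(fr, mutant_saml_frac = object@mutant_saml_frac)
  bad <- names(fr)[fr < 0 | fr > 1 | is.na(fr)]
  if (length(bad))
    return(sprintf("fraction slots out of [0,1]: %s", paste(bad, collapse = ", ")))
  if (object@me3_global_loss <= 0) return("me3_global_loss must be > 0")
  if (object@me3_planted_extra_loss <= 0) return("me3_planted_extra_loss must be > 0")
  if (object@ac_gain <= 0) return("ac_gain must be > 0")
  if (object@expr_effect < 1) return("expr_effect must be >= 1")
  if (object@n_h3_mutant > object@n_samples)
    return("n_h3_mutant must be <= n_samples")
  if (object@frac_up > 0.5)
    return("frac_up must be <= 0.5: planted up and down gene sets are disjoint")
  if (!is.na(object@mutant_saml_frac) &&
      round(object@n_h3_mutant * object@mutant_saml_frac) >
      round(object@n_samples * object@saml_frac))
    return("more mutant s-AML samples requested than s-AML samples exist")
  if (is.null(names(object@engraft_group_means)) ||
      any(!nzchar(names(object@engraft_group_means))))
    return("engraft_group_means must be a named numeric vector")
  TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed integer random seed.
#' @param n_samples,saml_frac,n_h3_mutant,mutant_saml_frac,depth_mean cohort
#'   layer parameters.
#' @param n_genes,frac_up gene universe and planted up-set size.
#' @param me3_global_loss,me3_planted_extra_loss,ac_gain,spike_frac,reads_per_library
#'   ChIP-Rx layer parameters.
#' @param expr_effect,expr_cv,n_replicates expression layer parameters.
#' @param engraft_group_means,engraft_sd,n_mice_per_group engraftment layer.
#' @param deterministic if TRUE, sampling is replaced by expectations.
#' @return A validated \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig(seed = 7)
#' @export
simulationConfig <- function(seed = 1L,
                             n_samples = 434, saml_frac = 0.076,
                             n_h3_mutant = 7, mutant_saml_frac = 3 / 7,
                             depth_mean = 7000,
                             n_genes = 500, frac_up = 0.1,
                             me3_global_loss = 0.5,
                             me3_planted_extra_loss = 0.5,
                             ac_gain = 2,
                             spike_frac = 0.02, reads_per_library = 1e5,
                             expr_effect = 4, expr_cv = 0.1, n_replicates = 3,
                             engraft_group_means = c(WT = 0.63, MUT = 29.8),
                             engraft_sd = 10, n_mice_per_group = 6,
                             deterministic = FALSE) {
  new("SimulationConfig", seed = as.integer(seed),
      n_samples = n_samples, saml_frac = saml_frac,
      n_h3_mutant = n_h3_mutant,
      mutant_saml_frac = as.numeric(mutant_saml_frac),
      depth_mean = depth_mean, n_genes = n_genes, frac_up = frac_up,
      me3_global_loss = me3_global_loss,
      me3_planted_extra_loss = me3_planted_extra_loss, ac_gain = ac_gain,
      spike_frac = spike_frac, reads_per_library = reads_per_library,
      expr_effect = expr_effect, expr_cv = expr_cv, n_replicates = n_replicates,
      engraft_group_means = engraft_group_means, engraft_sd = engraft_sd,
      n_mice_per_group = n_mice_per_group, deterministic = deterministic)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig (seed", object@seed, ")\n")
  cat(sprintf("  cohort: %d samples, %.1f%% s-AML, %d H3 mutants (%.0f%% in s-AML), depth %g\n",
              as.integer(object@n_samples), 100 * object@saml_frac,
              as.integer(object@n_h3_mutant), 100 * object@mutant_saml_frac,
              object@depth_mean))
  cat(sprintf("  chip:   %d genes, %g reads/library, spike %.1f%%, me3 loss %.2f (x%.2f planted), ac gain %.2f\n",
              as.integer(object@n_genes), object@reads_per_library,
              100 * object@spike_frac, object@me3_global_loss,
              object@me3_planted_extra_loss, object@ac_gain))
  cat(sprintf("  rna:    effect %.1fx, CV %.2f, %d replicates, %.0f%% planted up\n",
              object@expr_effect, object@expr_cv,
              as.integer(object@n_replicates), 100 * object@frac_up))
  cat(sprintf("  mice:   %d/group, means {%s}, sd %.1f\n",
              as.integer(object@n_mice_per_group),
              paste(sprintf("%s=%.2f", names(object@engraft_group_means),
                            object@engraft_group_means), collapse = ", "),
              object@engraft_sd))
  if (object@deterministic) cat("  deterministic mode: sampling replaced by expectations\n")
})

#' Per-library read accounting through the ChIP quantification chain
#'
#' Tracks read counts as a library passes deduplication, the mapping-quality
#' filter and the target/spike-in split. Validity enforces
#' n_raw >= n_dedup >= n_pass_mq = n_target + n_spike.
#'
#' @slot library_id library label.
#' @slot n_raw,n_dedup,n_pass_mq,n_target,n_spike read counts at each stage.
#' @export
setClass("LibraryStats", representation(
  library_id = "character",
  n_raw = "numeric", n_dedup = "numeric", n_pass_mq = "numeric",
  n_target = "numeric", n_spike = "numeric"
))

setValidity("LibraryStats", function(object) {
  if (any(c(object@n_raw, object@n_dedup, object@n_pass_mq,
            object@n_target, object@n_spike) < 0))
    return("all counts must be non-negative")
  if (object@n_raw < object@n_dedup) return("n_raw must be >= n_dedup")
  if (object@n_dedup < object@n_pass_mq) return("n_dedup must be >= n_pass_mq")
  if (object@n_pass_mq != object@n_target + object@n_spike)
    return("n_pass_mq must equal n_target + n_spike")
  TRUE
})

#' Construct LibraryStats
#' @param library_id library label.
#' @param n_raw,n_dedup,n_pass_mq,n_target,n_spike stage read counts.
#' @return A validated \linkS4class{LibraryStats}.
#' @export
libraryStats <- function(library_id, n_raw, n_dedup, n_pass_mq, n_target, n_spike) {
  new("LibraryStats", library_id = library_id, n_raw = n_raw, n_dedup = n_dedup,
      n_pass_mq = n_pass_mq, n_target = n_target, n_spike = n_spike)
}

#' @describeIn libraryStats number of spike-in reads (the Rx denominator).
#' @param x a LibraryStats object.
#' @export
nSpike <- function(x) x@n_spike

#' @describeIn libraryStats number of target-species reads passing filters.
#' @export
nTarget <- function(x) x@n_target

setMethod("show", "LibraryStats", function(object) {
  cat(sprintf("LibraryStats '%s': raw %d -> dedup %d -> MQ-pass %d (target %d + spike %d)\n",
              object@library_id, as.integer(object@n_raw),
              as.integer(object@n_dedup), as.integer(object@n_pass_mq),
              as.integer(object@n_target), as.integer(object@n_spike)))
})
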