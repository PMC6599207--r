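## Differential layer: z-score statistic, triplicate t-test, threshold
## calls, set overlaps, Tukey box/notch statistics and mark integration.

#' Mutant-vs-WT z-score statistic
#'
#' \code{z = (M - W) / sqrt(|M| + |W|)} with
#' \code{absoluteDenominator = TRUE} (ChIP net signal, which may be negative
#' after input subtraction) or \code{z = (M - W) / sqrt(M + W)} with
#' \code{absoluteDenominator = FALSE} (RNA abundance, non-negative).
#' When the denominator is 0 the score is defined as 0: such genes are
#' silent in both conditions.
#'
#' @param mutantMean,wtMean per-gene mean signal (vectorized).
#' @param absoluteDenominator use |M| + |W| under the square root.
#' @return numeric z-scores.
#' @examples
#' zScore(4, 1, absoluteDenominator = FALSE)  # 3/sqrt(5)
#' @export
zScore <- function(mutantMean, wtMean, absoluteDenominator = TRUE) {
  if (!absoluteDenominator && (any(mutantMean < 0) || any(wtMean < 0)))
    stop("usage error: RNA-mode z-score requires non-negative inputs",
         call. = FALSE)
  denom <- if (absoluteDenominator) sqrt(abs(mutantMean) + abs(wtMean))
           else sqrt(mutantMean + wtMean)
  ifelse(denom == 0, 0, (mutantMean - wtMean) / denom)
}

#' Two-tailed unpaired Student t-test (equal variance)
#'
#' Classical two-sample t with pooled variance and df = n1 + n2 - 2.
#' Degenerate rule when the pooled variance is exactly 0: p = 1 if the group
#' means are equal, else p = 0.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with statistic (t), p.value, method, n1, n2.
#' @export
tTestTwoSample <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("usage error: each group needs at least 2 observations", call. = FALSE)
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled == 0) {
    eq <- mean(a) == mean(b)
    return(list(statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                p.value = if (eq) 1 else 0,
                method = "student_t_two_sided",
                n1 = length(a), n2 = length(b)))
  }
  ht <- t.test(a, b, var.equal = TRUE)
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value),
       method = "student_t_two_sided", n1 = length(a), n2 = length(b))
}

#' Differential expression calls from replicate RPKM
#'
#' Replicates are averaged before the z-score is computed (RNA mode,
#' non-negative denominator); the p-value comes from the two-tailed
#' equal-variance t-test on the replicate values. A gene is called
#' \code{up} iff \code{z > zThresh} and \code{p < pThresh} (strict
#' inequalities), \code{down} symmetrically, otherwise \code{ns}. The
#' default thresholds are |z| > 1.5 with p < 0.05; the expanded analysis
#' uses zThresh = 0.8.
#'
#' @param mutant,wt numeric matrices gene x replicate with identical
#'   rownames (gene ids).
#' @param zThresh z-score threshold (default 1.5).
#' @param pThresh p-value threshold (default 0.05).
#' @return data.frame with gene_id, modality, mutant_mean, wt_mean, z, p,
#'   call.
#' @export
callDifferential <- function(mutant, wt, zThresh = 1.5, pThresh = 0.05) {
  if (is.null(rownames(mutant)) || is.null(rownames(wt)) ||
      !identical(sort(rownames(mutant)), sort(rownames(wt))))
    stop("validation error: mutant and WT matrices must cover the same genes",
         call. = FALSE)
  wt <- wt[rownames(mutant), , drop = FALSE]
  m_mean <- rowMeans(mutant)
  w_mean <- rowMeans(wt)
  z <- zScore(m_mean, w_mean, absoluteDenominator = FALSE)
  p <- vapply(seq_len(nrow(mutant)), function(i)
    tTestTwoSample(mutant[i, ], wt[i, ])$p.value, numeric(1))
  call <- rep("ns", length(z))
  call[z > zThresh & p < pThresh] <- "up"
  call[z < -zThresh & p < pThresh] <- "down"
  data.frame(gene_id = rownames(mutant), modality = "rna",
             mutant_mean = unname(m_mean), wt_mean = unname(w_mean),
             z = unname(z), p = p,
             call = factor(call, levels = c("up", "down", "ns")),
             stringsAsFactors = FALSE)
}

#' Overlap of differential gene sets from two comparisons
#'
#' Partitions the genes carrying the given call in either comparison into
#' three disjoint sets.
#'
#' @param callsA,callsB data.frames from \code{\link{callDifferential}}
#'   (same modality).
#' @param direction "up" or "down".
#' @return list with only_a, shared, only_b (character vectors of gene ids).
#' @export
overlapSets <- function(callsA, callsB, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (!identical(unique(callsA$modality), unique(callsB$modality)))
    stop("usage error: overlap requires the same modality", call. = FALSE)
  ga <- callsA$gene_id[callsA$call == direction]
  gb <- callsB$gene_id[callsB$call == direction]
  list(only_a = setdiff(ga, gb), shared = intersect(ga, gb),
       only_b = setdiff(gb, ga))
}

#' Tukey box-and-whisker statistics with notches
#'
#' Hinges are Tukey hinges (\code{\link[stats]{fivenum}}): medians of the
#' lower and upper halves with the overall median included in both halves
#' when n is odd. Whiskers reach to the most extreme data point within
#' hinge +/- 1.5 * IQR, and notches extend to
#' median +/- 1.58 * IQR / sqrt(n), an approximate 95\% confidence interval
#' for the median.
#'
#' @param values numeric vector, length >= 1.
#' @return one-row data.frame with n, median, hinge_lo, hinge_hi, iqr,
#'   whisker_lo, whisker_hi, notch_lo, notch_hi.
#' @examples
#' boxStats(1:9)
#' @export
boxStats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values))
    stop("usage error: box statistics need at least one value", call. = FALSE)
  fn <- fivenum(values)
  hinge_lo <- fn[2]; med <- fn[3]; hinge_hi <- fn[4]
  iqr <- hinge_hi - hinge_lo
  whisker_hi <- max(values[values <= hinge_hi + 1.5 * iqr])
  whisker_lo <- min(values[values >= hinge_lo - 1.5 * iqr])
  notch <- 1.58 * iqr / sqrt(length(values))
  data.frame(n = length(values), median = med,
             hinge_lo = hinge_lo, hinge_hi = hinge_hi, iqr = iqr,
             whisker_lo = whisker_lo, whisker_hi = whisker_hi,
             notch_lo = med - notch, notch_hi = med + notch)
}

#' Promoter-set H3K27me3 shift versus the global promoter distribution
#'
#' Compares the z-score distribution of a gene subset (e.g. the promoters of
#' genes upregulated in both mutants) against all promoters, via Tukey
#' box/notch statistics. The shift flag reports whether the subset median
#' lies below the global notch interval.
#'
#' @param me3ZByGene named numeric vector of per-gene ChIP z-scores.
#' @param geneSet character vector of gene ids, a subset of
#'   \code{names(me3ZByGene)}.
#' @return list with \code{global} and \code{subset} box statistics and
#'   logical \code{shift}.
#' @export
promoterSetShift <- function(me3ZByGene, geneSet) {
  if (!length(geneSet))
    stop("usage error: empty gene set", call. = FALSE)
  if (!all(geneSet %in% names(me3ZByGene)))
    stop("usage error: gene set must be a subset of the scored genes",
         call. = FALSE)
  global <- boxStats(unname(me3ZByGene))
  subset <- boxStats(unname(me3ZByGene[geneSet]))
  list(global = global, subset = subset,
       shift = subset$median < global$notch_lo)
}

#' Integrate H3K27me3, H3K27ac and RNA z-scores per gene
#'
#' Classifies each gene by the sign pattern of its three z-scores into one
#' of five exhaustive, mutually exclusive categories:
#' \code{derepressed_activated} (me3 loss, ac gain, RNA up),
#' \code{me3_loss_only}, \code{ac_gain_only}, \code{unchanged} (all three
#' within +/- eps) and \code{other}.
#'
#' @param me3Z,acZ,rnaZ named numeric vectors over the same gene universe.
#' @param eps half-width of the "no change" band (default 0: pure sign test).
#' @return named factor of categories.
#' @export
integrateMarks <- function(me3Z, acZ, rnaZ, eps = 0) {
  genes <- names(me3Z)
  if (is.null(genes) || !setequal(genes, names(acZ)) || !setequal(genes, names(rnaZ)))
    stop("usage error: the three z maps must share one gene universe",
         call. = FALSE)
  acZ <- acZ[genes]; rnaZ <- rnaZ[genes]
  cat_ <- rep("other", length(genes))
  cat_[abs(me3Z) <= eps & abs(acZ) <= eps & abs(rnaZ) <= eps] <- "unchanged"
  cat_[acZ > eps & !(me3Z < -eps)] <- "ac_gain_only"
  cat_[me3Z < -eps & !(acZ > eps)] <- "me3_loss_only"
  cat_[me3Z < -eps & acZ > eps & rnaZ > eps] <- "derepressed_activated"
  setNames(factor(cat_, levels = c("derepressed_activated", "me3_loss_only",
                                   "ac_gain_only", "unchanged", "other")),
           genes)
}
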