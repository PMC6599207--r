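suppressPackageStartupMessages(library(GenomicRanges))

# Independent brute-force oracles, kept deliberately separate from the
# implementation paths they check.

# Two-sided Fisher p by hypergeometric enumeration over all tables with the
# observed margins: sum of point probabilities <= observed (1+1e-7 slack).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c_; n <- a + b + c_ + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  support <- lo:hi
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments, with U
# computed by direct pairwise comparison (not ranks).
mw_oracle <- function(a, b) {
  u_pairwise <- function(x, y) {
    # #{(i,j): y_i > x_j} + 0.5 * ties
    sum(outer(y, x, ">")) + 0.5 * sum(outer(y, x, "=="))
  }
  pooled <- c(a, b)
  n <- length(pooled); n1 <- length(a); n2 <- length(b)
  u <- u_pairwise(a, b)
  idx <- combn(n, n2)
  us <- apply(idx, 2, function(ix) u_pairwise(pooled[-ix], pooled[ix]))
  lo <- min(u, n1 * n2 - u); hi <- max(u, n1 * n2 - u)
  list(u = u, p = min(1, (sum(us <= lo) + sum(us >= hi)) / ncol(idx)))
}

# Tukey box/notch statistics from first principles (sorting + half medians).
box_oracle <- function(x) {
  x <- sort(x); n <- length(x)
  med <- median(x)
  h <- ceiling(n / 2)                       # lower half, median included if odd
  hinge_lo <- median(x[1:h])
  hinge_hi <- median(x[(n - h + 1):n])
  iqr <- hinge_hi - hinge_lo
  list(n = n, median = med, hinge_lo = hinge_lo, hinge_hi = hinge_hi,
       iqr = iqr,
       whisker_lo = min(x[x >= hinge_lo - 1.5 * iqr]),
       whisker_hi = max(x[x <= hinge_hi + 1.5 * iqr]),
       notch_lo = med - 1.58 * iqr / sqrt(n),
       notch_hi = med + 1.58 * iqr / sqrt(n))
}

# Minimal helpers to build in-memory records used across test files.
make_variants <- function(vaf, alt_reads = round(vaf * 1000), depth = 1000,
                          assay = "targeted", sample_id = "S1",
                          chrom = "chr6", pos = seq_along(vaf),
                          callers = "") {
  data.frame(sample_id = sample_id, gene = "HIST1H3F", protein_change = "K27I",
             chrom = chrom, pos = pos, ref = "A", alt = "T",
             alt_reads = alt_reads, depth = depth, vaf = vaf,
             callers = callers, assay = assay, stringsAsFactors = FALSE)
}

make_reads <- function(chrom, start0, end0, strand = "+", mapq = 60,
                       species = NULL) {
  sp <- if (is.null(species)) ifelse(startsWith(chrom, "dmel_"),
                                     "spikein", "target") else species
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         strand = strand,
                         name = sprintf("r%d", seq_along(chrom)),
                         mapq = as.integer(mapq),
                         species = factor(sp, levels = c("target", "spikein")))
}
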