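---
title: "Methods: oncohistone screening, ChIP-Rx quantification and the synthetic study generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oncohistone screening, ChIP-Rx quantification and the synthetic study generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind each exported
computation, the assumptions of the synthetic study generator, and the
numerical conventions the package commits to. Nothing here asserts an
empirical result that is not computed by the test suite or by
`scripts/acceptance.R`.

# Variant screening

Targeted (amplicon) calls are retained when all of the following hold:
variant allele frequency (VAF) `>= targeted_min_vaf` (default 0.10),
alternate-supporting reads `>= targeted_min_alt` (default 20), and the site
is not on the supplied blacklist (a stand-in for common-polymorphism
databases). The filter is a pure subset operation: order-preserving,
idempotent, and monotone in both thresholds.

Exome calls are accepted by consensus: a variant must be reported by at
least `exome_min_callers` (default 2) of the supplied per-caller tables and
reach `exome_min_support` (default 0.20) supporting-read fraction in at
least one caller. The consensus record carries the union of caller labels
and the read counts of the maximum-depth observation, so depth is never
double-counted across callers.

Clonality uses two VAF thresholds on diagnosis/remission pairs. A variant
still detectable at VAF `>= detect_min_vaf` (0.10) in the remission sample
is classified `pre_leukemic` — the mutation precedes the leukemic clone and
survives therapy; otherwise `leukemia_restricted`, or `undetermined` when no
remission sample exists. Independently, diagnosis VAF `>= major_clone_min_vaf`
(0.35) assigns the variant to the `major` clone, the heterozygous-range
expectation for a lesion present in nearly all blasts.

# Cohort statistics

`buildContingency` excludes remission rows (they duplicate patients) and
cross-tabulates two user predicates. `fisherExactTwoSided` delegates to
`stats::fisher.test`: its two-sided rule — summing hypergeometric point
probabilities not exceeding the observed one, with a `1 + 1e-7` relative
slack — is exactly the convention this package specifies, so wrapping it is
preferable to re-deriving it. The reported statistic is the sample odds
ratio `ad/bc` (`Inf` when `bc = 0`), not the conditional MLE that
`fisher.test` estimates. An independent brute-force hypergeometric
enumeration oracle lives in the test helpers and is checked against the
wrapper exhaustively for small table totals and on random larger tables.

# ChIP-Rx promoter quantification

The chain is fixed, in this order:

1. **Deduplication**: reads identical in (chromosome, start, end, strand)
   collapse to their first occurrence. Strand is part of the key by default
   because opposite-strand reads at one locus are distinct molecules;
   `ignoreStrand = TRUE` reproduces tools that drop it.
2. **MAPQ filter**: strictly `mapq > 5`. A read with MAPQ exactly 5 is
   removed.
3. **3′ extension**: each read is extended 250 bp in its 3′ direction to
   approximate the sequenced fragment (plus strand: `[s, e + 250)`; minus:
   `[max(0, s - 250), e)`), clipped at position 0. The alternative
   `mode = "resize"` instead fixes the total length at 250 bp anchored at
   the 5′ end, a convention some pipelines use; clipping can shorten it.
4. **Window counting**: promoter windows are `[tss - 1500, tss + 1500)`
   (half-open, 0-based). A read counts in every window it overlaps by at
   least 1 bp; windows are independent, so one read may count twice.
5. **Rx normalization**: `rx = count * 1e9 / (window_len * n_spike)` where
   `n_spike` is the number of spike-in–species reads passing steps 1–2.
   This is RPKM with the spike-in library as the "per million" denominator.
   Because the spike-in chromatin share is constant across conditions, `rx`
   is invariant under joint scaling of sequencing depth (property-tested)
   and *does* move when the target genome globally loses signal — which
   target-library RPKM cannot detect by construction.
6. **Input subtraction**: `net = rx_chip - rx_input` per gene; negative
   values are preserved (flooring at zero would bias the z-score
   denominator).
7. **Replicate averaging**: arithmetic mean per gene, labelled
   `replicate = "averaged"`.

`LibraryStats` tracks read accounting and enforces
`n_raw >= n_dedup >= n_pass_mq = n_target + n_spike` as a class invariant.

# Differential statistics

Expression z-scores use `z = (M - W) / sqrt(M + W)` on non-negative
abundances; ChIP z-scores use `z = (M - W) / sqrt(|M| + |W|)` because
input-subtracted signal may be negative. A zero denominator yields `z = 0`:
a gene silent in both conditions carries no evidence of change. The
replicate test is Student's equal-variance t-test (`stats::t.test`,
`var.equal = TRUE`) — with 2–3 replicates per condition, per-gene variance
estimates are too unstable for Welch — with degenerate conventions: zero
pooled variance gives `p = 1` when means are equal and `p = 0` otherwise.
Calls are strict: `up` iff `z > zThresh` **and** `p < pThresh` (defaults
1.5 and 0.05; an expanded threshold of 0.8 can be supplied for overlap
analyses).

Box statistics follow Tukey: hinges from `stats::fivenum` (half-sample
medians), whiskers at the most extreme data within hinge ± 1.5·IQR, and
notches at median ± 1.58·IQR/√n, the standard approximate 95% interval for
the median. `promoterSetShift` flags a gene set whose median lies below the
lower notch of the global distribution — a conservative, plot-derived
criterion for "this promoter set shifted down". `integrateMarks` classifies
genes by the signs of their H3K27me3, H3K27ac and RNA z-scores; the
interesting class `derepressed_activated` (me3 loss + ac gain + RNA up)
reflects the mutual exclusivity of methylation and acetylation at H3K27.

# Engraftment

A mouse is engrafted iff its percent human chimerism strictly exceeds 1%.
The group comparison is a two-sided Mann–Whitney U test with
`U = #{(b, a) : b > a} + ties/2`, computed via midranks. For groups of at
most 10 the p-value is exact: all `choose(n1 + n2, n2)` label assignments of
the pooled values are enumerated and
`p = P(U <= min(u, n1*n2 - u)) + P(U >= max(u, n1*n2 - u))`, capped at 1.
This is hand-rolled because `stats::wilcox.test` refuses exact p-values in
the presence of ties, and tied engraftment values occur in practice; the
test suite checks it against `wilcox.test`'s tie-corrected normal
approximation on large samples and against an independent pairwise-counting
enumeration oracle on all small group-size combinations.

# The synthetic study generator

Every generator is a pure function of a `SimulationConfig` (seed included);
`deterministic = TRUE` replaces sampling by expectations for exact unit
tests. Defaults describe the emulated study: a 434-sample cohort with 7.6%
secondary AML and seven H3-mutant samples (three of them s-AML) at
heterozygous-range VAFs (uniform on 0.40–0.55) under deep targeted coverage
(Poisson mean 7000); ChIP libraries of 100,000 50 bp single-end reads with
2% spike-in; a 500-gene universe with 10% planted up-regulated genes; a
two-fold global H3K27me3 loss with an extra two-fold loss at planted
up-genes; two-fold promoter H3K27ac gain at those genes; four-fold planted
expression changes with 10% replicate CV; and two engraftment arms of six
mice with means 0.63% and 29.8% (truncated normal on [0, 100] via inverse
CDF, SD 10).

Key modelling choices:

- **Library shrinkage under loss.** Spike-in reads are
  `Binomial(N, spike_frac)` in every library — the constant-spike premise
  of ChIP-Rx. Per-gene promoter reads are Poisson with intensity
  proportional to the gene's mark level times its loss factor, so a global
  loss *shrinks* the mutant target library instead of redistributing a
  fixed read total. With a fixed library size and fixed spike fraction, Rx
  normalization could detect nothing; the shrinkage is precisely the signal
  it measures.
- **Background-matched inputs.** ChIP libraries carry 30% uniform
  background reads; input libraries carry background and spike-in only, at
  the same normalized background density, so input subtraction removes
  exactly the non-specific component in expectation.
- **Planted genes sit atop the repressive mark.** Planted up-genes are the
  top `frac_up` of the H3K27me3 intensity distribution and receive
  `me3_planted_extra_loss` on top of the global factor. This encodes the
  biological picture — genes de-repressed by H3K27me3 loss are those whose
  promoters carried the mark — and is what makes the inverse me3/RNA
  correlation and the promoter-set shift recoverable at all. Intensities
  and baseline expression are log-normal stand-ins for genomic abundance
  distributions.
- **The unstructured null.** Setting `mutant_saml_frac = NA` places mutant
  samples uniformly at random across diagnoses. Note that exact Fisher
  p-values on a discrete 2×2 null are conservative (stochastically larger
  than uniform), so the calibration check bounds the rejection rate at the
  nominal level rather than testing p-value uniformity — uniformity is
  unattainable for this statistic by construction.
- **Null calibration bound.** The expression null check (all effects 1)
  pools 20 seeds × 500 genes and requires the called fraction at
  `p < 0.05` (no z gate) to fall inside the two-sided 99% normal-binomial
  interval around 0.05. The interval was fixed a priori, before the check
  was first run.

Problem sizes in the tests and the acceptance script (gene-universe sizes,
read depths, seed counts) are this package's own choices, balancing
statistical resolution against runtime.

# Limitations

The generator validates the *pipeline*, not the biology: passing recovery
checks on synthetic data shows the chain of dedup → filter → count →
normalize → subtract → average → call is implemented coherently and can
detect the effects it models, under idealized assumptions (uniform read
placement within promoters, Poisson counts, condition-independent spike-in,
no GC or mappability structure, no antibody-efficiency variation). Real
ChIP-Rx data violate all of these to some degree; effect-size estimates
from real data should not inherit the synthetic error rates. The exact
tests, by contrast, are distribution-free and carry over directly.
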