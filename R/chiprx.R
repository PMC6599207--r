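## Spike-in (ChIP-Rx) promoter quantification chain:
## dedup -> MAPQ filter + 250 bp extension -> 3 kb TSS window counts ->
## spike-in normalization -> input subtraction -> replicate averaging.

#' Remove PCR duplicates
#'
#' Reads with identical coordinates are collapsed to their first occurrence.
#' By default the duplicate key is (chrom, start, end, strand): identical
#' coordinates on opposite strands are distinct molecules for single-end
#' data. Set \code{ignoreStrand = TRUE} to collapse across strands.
#'
#' @param reads GRanges of one library's reads.
#' @param ignoreStrand drop strand from the duplicate key.
#' @return list with \code{reads} (deduplicated GRanges), \code{n_raw} and
#'   \code{n_dedup}.
#' @export
dedupReads <- function(reads, ignoreStrand = FALSE) {
  if (!length(reads))
    return(list(reads = reads, n_raw = 0L, n_dedup = 0L))
  key <- paste(as.character(seqnames(reads)), start(reads), end(reads),
               if (ignoreStrand) "" else as.character(strand(reads)))
  keep <- !duplicated(key)
  list(reads = reads[keep], n_raw = length(reads), n_dedup = sum(keep))
}

#' Mapping-quality filter and fragment extension
#'
#' Drops reads whose mapping quality does not exceed \code{minMapq} (strict:
#' the default keeps MQ > 5 only) and extends survivors by \code{ext} bp in
#' the 3' direction: a plus-strand read [s, e) becomes [s, e + ext) and a
#' minus-strand read becomes [max(0, s - ext), e). With
#' \code{mode = "resize"} reads are instead resized to \code{ext} bp total,
#' anchored at their 5' end.
#'
#' @param reads deduplicated GRanges with an \code{mapq} metadata column.
#' @param minMapq reads must have mapq strictly greater than this (default 5).
#' @param ext extension length in bp (default 250).
#' @param mode "extend" (3' extension, default) or "resize" (fixed total
#'   fragment length).
#' @return filtered, extended GRanges.
#' @export
filterAndExtend <- function(reads, minMapq = 5, ext = 250,
                            mode = c("extend", "resize")) {
  mode <- match.arg(mode)
  reads <- reads[mcols(reads)$mapq > minMapq]
  if (!length(reads)) return(reads)
  plus <- as.character(strand(reads)) == "+"
  s <- start(reads); e <- end(reads)
  if (mode == "extend") {
    e[plus] <- e[plus] + ext
    s[!plus] <- pmax(1, s[!plus] - ext)
  } else {
    e[plus] <- s[plus] + ext - 1
    s[!plus] <- pmax(1, e[!plus] - ext + 1)
  }
  out <- GRanges(seqnames(reads), IRanges(s, e), strand = strand(reads))
  mcols(out) <- mcols(reads)
  out
}

#' Count reads per promoter window
#'
#' A read increments a gene's count iff its interval overlaps the gene's
#' window by at least 1 bp; a read overlapping several windows counts toward
#' each of them. Strand is ignored.
#'
#' @param reads extended target-species GRanges.
#' @param promoters promoter-window GRanges from
#'   \code{\link{promoterWindows}}.
#' @return named numeric vector of counts, one per gene_id.
#' @export
windowCounts <- function(reads, promoters) {
  n <- countOverlaps(promoters, reads, minoverlap = 1, ignore.strand = TRUE)
  setNames(as.numeric(n), mcols(promoters)$gene_id)
}

#' Spike-in (Rx) normalization of a window count
#'
#' Reads per kb of window per million spike-in reads:
#' \code{count * 1e9 / (window_len * n_spike)} — RPKM with the spike-in
#' library size as denominator. Because the spike-in chromatin is a fixed
#' share of every sample, this scale is comparable across conditions and
#' reveals global signal loss that library-size normalization would hide.
#'
#' @param count window read count (vectorized).
#' @param windowLen window length in bp.
#' @param stats a \code{\link{libraryStats}} object, or a bare spike-in read
#'   count.
#' @return normalized signal (same length as count).
#' @export
rxNormalize <- function(count, windowLen, stats) {
  ns <- if (is(stats, "LibraryStats")) nSpike(stats) else stats
  if (ns <= 0) {
    id <- if (is(stats, "LibraryStats")) stats@library_id else "<unnamed>"
    stop(sprintf("normalization error: library '%s' has no spike-in reads", id),
         call. = FALSE)
  }
  count * 1e9 / (windowLen * ns)
}

#' Subtract input (non-specific) signal from ChIP signal
#'
#' Net signal = ChIP rx_signal - input rx_signal at the same gene. Negative
#' values are preserved (no flooring); this is why the downstream ChIP
#' z-score uses absolute values in its denominator.
#'
#' @param chip,input signal data.frames with columns gene_id and rx_signal,
#'   same genes in any order.
#' @return \code{chip} with a \code{net_signal} column added/overwritten.
#' @export
subtractInput <- function(chip, input) {
  if (!setequal(chip$gene_id, input$gene_id) ||
      nrow(chip) != nrow(input))
    stop("usage error: ChIP and input signal must cover the same genes",
         call. = FALSE)
  inp <- setNames(input$rx_signal, input$gene_id)
  chip$net_signal <- chip$rx_signal - unname(inp[chip$gene_id])
  chip
}

#' Average technical replicates of a signal table
#'
#' Arithmetic mean of rx_signal and net_signal per gene; requires all records
#' to share one (mark, condition) pair. The result carries
#' \code{replicate = "averaged"}.
#'
#' @param records signal data.frame with one row per (gene, replicate).
#' @return averaged signal data.frame, one row per gene.
#' @export
averageReplicates <- function(records) {
  if (!nrow(records))
    stop("usage error: no signal records to average", call. = FALSE)
  if (length(unique(records$condition)) > 1 || length(unique(records$mark)) > 1)
    stop("usage error: mixed conditions or marks in replicate averaging",
         call. = FALSE)
  agg <- aggregate(records[c("raw_count", "rx_signal", "net_signal")],
                   by = list(gene_id = records$gene_id), FUN = mean)
  data.frame(gene_id = agg$gene_id, mark = records$mark[1],
             condition = records$condition[1], replicate = "averaged",
             raw_count = agg$raw_count, rx_signal = agg$rx_signal,
             net_signal = agg$net_signal, stringsAsFactors = FALSE)
}

#' Quantify one library's promoter signal
#'
#' Runs the fixed chain dedup -> MAPQ filter/extend -> target/spike split ->
#' window counts -> spike-in normalization for a single library and returns
#' the per-gene signal together with full read accounting.
#'
#' @param reads GRanges of the library's aligned reads (metadata columns
#'   mapq and species, as from \code{\link{readBedReads}}).
#' @param promoters promoter windows.
#' @param mark,condition,replicate labels stored in the output.
#' @param libraryId label used in error messages and accounting.
#' @param minMapq,ext,extMode,dedupIgnoreStrand see
#'   \code{\link{filterAndExtend}} and \code{\link{dedupReads}}.
#' @return list with \code{signal} (data.frame gene_id, mark, condition,
#'   replicate, raw_count, n_spike, rx_signal) and \code{stats}
#'   (\linkS4class{LibraryStats}).
#' @export
quantifyLibrary <- function(reads, promoters, mark, condition,
                            replicate = "rep1", libraryId = NULL,
                            minMapq = 5, ext = 250,
                            extMode = c("extend", "resize"),
                            dedupIgnoreStrand = FALSE) {
  extMode <- match.arg(extMode)
  if (is.null(libraryId))
    libraryId <- paste(condition, mark, replicate, sep = ".")
  dd <- dedupReads(reads, ignoreStrand = dedupIgnoreStrand)
  filt <- filterAndExtend(dd$reads, minMapq = minMapq, ext = ext, mode = extMode)
  species <- mcols(filt)$species
  target <- filt[species == "target"]
  n_spike <- sum(species == "spikein")
  stats <- libraryStats(libraryId, n_raw = dd$n_raw, n_dedup = dd$n_dedup,
                        n_pass_mq = length(filt),
                        n_target = length(target), n_spike = n_spike)
  counts <- windowCounts(target, promoters)
  rx <- rxNormalize(counts, width(promoters), stats)
  signal <- data.frame(gene_id = names(counts), mark = mark,
                       condition = condition, replicate = replicate,
                       raw_count = unname(counts), n_spike = n_spike,
                       rx_signal = unname(rx), stringsAsFactors = FALSE)
  list(signal = signal, stats = stats)
}

#' Full ChIP-Rx promoter pipeline for one (condition, mark)
#'
#' Quantifies each ChIP replicate and the matched input library, subtracts
#' the input's normalized signal from each replicate, and averages the
#' replicates.
#'
#' @param chipReads named list of GRanges, one per ChIP technical replicate.
#' @param inputReads GRanges of the matched input library.
#' @param promoters promoter windows.
#' @param mark,condition labels.
#' @param ... passed to \code{\link{quantifyLibrary}}.
#' @return list with \code{signal} (averaged per-gene data.frame including
#'   net_signal), \code{replicates} (per-replicate signal, input-subtracted)
#'   and \code{stats} (list of LibraryStats, one per library).
#' @export
chipRxPromoterSignal <- function(chipReads, inputReads, promoters,
                                 mark, condition, ...) {
  if (!length(chipReads))
    stop("usage error: at least one ChIP replicate is required", call. = FALSE)
  if (is.null(names(chipReads)))
    names(chipReads) <- sprintf("rep%d", seq_along(chipReads))
  input <- quantifyLibrary(inputReads, promoters, mark, condition,
                           replicate = "input", ...)
  reps <- lapply(names(chipReads), function(rn) {
    q <- quantifyLibrary(chipReads[[rn]], promoters, mark, condition,
                         replicate = rn, ...)
    q$signal <- subtractInput(q$signal, input$signal)
    q
  })
  per_rep <- do.call(rbind, lapply(reps, `[[`, "signal"))
  stats <- c(lapply(reps, `[[`, "stats"), list(input = input$stats))
  names(stats) <- c(names(chipReads), "input")
  list(signal = averageReplicates(per_rep), replicates = per_rep,
       stats = stats)
}
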