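## Variant retention rules and VAF-based clonality classification.

.variant_key <- function(calls, with_sample = TRUE) {
  if (with_sample)
    paste(calls$sample_id, calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  else
    paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
}

.blacklist_key <- function(blacklist) {
  if (!nrow(blacklist)) return(character())
  paste(blacklist$chrom, blacklist$pos, blacklist$ref, blacklist$alt, sep = "\r")
}

#' Retention filter for targeted (deep amplicon) variant calls
#'
#' Retains calls with VAF at or above \code{targeted_min_vaf} (default 10\%)
#' that are supported by at least \code{targeted_min_alt} alternate reads
#' (default 20) and whose site is not on the common-polymorphism blacklist.
#' Input order is preserved and the filter is idempotent.
#'
#' @param calls data.frame of variant calls with \code{assay == "targeted"}.
#' @param config a \code{\link{screenConfig}}.
#' @return the retained subset of \code{calls}.
#' @export
filterTargetedVariants <- function(calls, config = screenConfig()) {
  stopifnot(is(config, "ScreenConfig"))
  if (!nrow(calls)) return(calls)
  if (any(calls$assay != "targeted"))
    stop("usage error: filterTargetedVariants applies to targeted calls only",
         call. = FALSE)
  keep <- calls$vaf >= config@targeted_min_vaf &
    !is.na(calls$alt_reads) & calls$alt_reads >= config@targeted_min_alt &
    !(.variant_key(calls, with_sample = FALSE) %in% .blacklist_key(config@blacklist))
  calls[keep, , drop = FALSE]
}

#' Consensus filtering of exome calls from multiple variant callers
#'
#' A variant (keyed by sample, chrom, pos, ref, alt) is emitted iff it was
#' called by at least \code{exome_min_callers} callers (default 2 of 3) and
#' its maximum reported VAF is at least \code{exome_min_support} (default
#' 20\% of reads supporting the call). The emitted record carries the union
#' of caller labels and the read counts of the maximum-depth observation.
#'
#' @param callsByCaller named list mapping caller label to a data.frame of
#'   variant calls (\code{assay == "exome"}).
#' @param config a \code{\link{screenConfig}}.
#' @return data.frame of consensus calls.
#' @export
consensusExomeCalls <- function(callsByCaller, config = screenConfig()) {
  stopifnot(is(config, "ScreenConfig"))
  if (!length(callsByCaller) || is.null(names(callsByCaller)))
    stop("usage error: supply a named list with at least two caller tables",
         call. = FALSE)
  if (length(callsByCaller) < 2)
    stop("usage error: consensus requires at least two callers", call. = FALSE)
  pooled <- do.call(rbind, lapply(names(callsByCaller), function(cl) {
    df <- callsByCaller[[cl]]
    if (!nrow(df)) return(NULL)
    df$caller <- cl
    df
  }))
  if (is.null(pooled) || !nrow(pooled)) return(callsByCaller[[1]][0, , drop = FALSE])
  key <- .variant_key(pooled)
  out <- do.call(rbind, lapply(split(seq_len(nrow(pooled)), key), function(ix) {
    obs <- pooled[ix, , drop = FALSE]
    callers <- unique(obs$caller)
    if (length(callers) < config@exome_min_callers) return(NULL)
    if (max(obs$vaf) < config@exome_min_support) return(NULL)
    rec <- obs[which.max(obs$depth), , drop = FALSE]
    rec$callers <- paste(sort(callers), collapse = ",")
    rec$caller <- NULL
    rec
  }))
  if (is.null(out)) out <- callsByCaller[[1]][0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify variant clonality from diagnosis and remission VAFs
#'
#' A variant detected in the paired remission sample at VAF >=
#' \code{detect_min_vaf} is classified \code{pre_leukemic} (it predates the
#' leukemic clone and persists in remission); one absent from a supplied
#' remission sample is \code{leukemia_restricted}; with no remission sample
#' the status is \code{undetermined}. Independently, a variant with diagnosis
#' VAF >= \code{major_clone_min_vaf} belongs to the \code{major} clone.
#'
#' @param dx data.frame of diagnosis-sample variant calls (non-empty).
#' @param remission optional data.frame of remission-sample calls for the
#'   same patient; NULL when no remission sample exists.
#' @param config a \code{\link{screenConfig}}.
#' @return data.frame with columns sample_id, gene, protein_change, variant
#'   (chrom:pos ref>alt), status, clone_class, dx_vaf, remission_vaf.
#' @export
classifyClonality <- function(dx, remission = NULL, config = screenConfig()) {
  stopifnot(is(config, "ScreenConfig"))
  if (!nrow(dx))
    stop("usage error: diagnosis call set must be non-empty", call. = FALSE)
  rem_key <- if (!is.null(remission) && nrow(remission))
    .variant_key(remission, with_sample = FALSE) else character()
  rem_vaf <- if (length(rem_key)) setNames(remission$vaf, rem_key) else numeric()
  key <- .variant_key(dx, with_sample = FALSE)
  rvaf <- unname(rem_vaf[key])
  status <- if (is.null(remission)) rep("undetermined", nrow(dx)) else
    ifelse(!is.na(rvaf) & rvaf >= config@detect_min_vaf,
           "pre_leukemic", "leukemia_restricted")
  data.frame(
    sample_id = dx$sample_id, gene = dx$gene,
    protein_change = dx$protein_change,
    variant = sprintf("%s:%s %s>%s", dx$chrom, dx$pos, dx$ref, dx$alt),
    status = factor(status, levels = c("pre_leukemic", "leukemia_restricted",
                                       "undetermined")),
    clone_class = factor(ifelse(dx$vaf >= config@major_clone_min_vaf,
                                "major", "minor"), levels = c("major", "minor")),
    dx_vaf = dx$vaf,
    remission_vaf = rvaf,
    stringsAsFactors = FALSE
  )
}
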