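## Cohort-level contingency tables, exact Fisher tests and incidences.

#' Build a 2x2 contingency table over cohort samples
#'
#' Remission samples are excluded (they duplicate their diagnosis sample's
#' patient). Cell layout: rows = predicate-positive/negative, columns =
#' group-positive/negative, i.e. \code{a = row & col}, \code{b = row & !col},
#' \code{c = !row & col}, \code{d = !row & !col}.
#'
#' @param samples data.frame from \code{\link{readSampleSheet}}.
#' @param rowPredicate,colPredicate functions mapping the sample data.frame
#'   to a logical vector (e.g. \code{function(s) s$k27_mutant}).
#' @return 2x2 integer matrix.
#' @examples
#' sheet <- readSampleSheet(system.file("extdata", "cohort_samples.tsv",
#'                                      package = "oncohistoneScreen"))
#' buildContingency(sheet, function(s) !is.na(s$h3_mutation),
#'                  function(s) s$diagnosis == "s_aml")
#' @export
buildContingency <- function(samples, rowPredicate, colPredicate) {
  if (!nrow(samples))
    stop("usage error: empty sample list", call. = FALSE)
  samples <- samples[samples$diagnosis != "remission", , drop = FALSE]
  if (!nrow(samples))
    stop("usage error: no non-remission samples", call. = FALSE)
  r <- rowPredicate(samples)
  k <- colPredicate(samples)
  stopifnot(is.logical(r), is.logical(k),
            length(r) == nrow(samples), length(k) == nrow(samples))
  matrix(c(sum(r & k), sum(r & !k), sum(!r & k), sum(!r & !k)),
         nrow = 2, byrow = TRUE,
         dimnames = list(row = c("pos", "neg"), col = c("pos", "neg")))
}

#' Two-sided exact Fisher test on a 2x2 table
#'
#' Exact p-value under the hypergeometric null with all margins fixed: the
#' sum of point probabilities of every table (same margins) whose point
#' probability does not exceed the observed one, up to a 1 + 1e-7 relative
#' tolerance. The reported statistic is the descriptive sample odds ratio
#' ad/bc (Inf when bc = 0).
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with statistic (odds ratio), p.value, method, n1, n2 (row
#'   totals).
#' @examples
#' fisherExactTwoSided(matrix(c(3, 4, 30, 397), 2, byrow = TRUE))
#' @export
fisherExactTwoSided <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)))
    stop("usage error: a 2x2 table is required", call. = FALSE)
  if (any(tab < 0) || any(is.na(tab)))
    stop("validation error: negative or missing cell counts", call. = FALSE)
  if (sum(tab) == 0)
    stop("validation error: table total must be > 0", call. = FALSE)
  ht <- fisher.test(tab, alternative = "two.sided")
  bc <- tab[1, 2] * tab[2, 1]
  or <- if (bc == 0) Inf else (tab[1, 1] * tab[2, 2]) / bc
  list(statistic = unname(or), p.value = unname(ht$p.value),
       method = "fisher_exact_two_sided",
       n1 = sum(tab[1, ]), n2 = sum(tab[2, ]))
}

#' Incidence of an event within a subgroup
#'
#' The fraction of subgroup samples in which the event predicate holds;
#' remission samples are excluded before evaluating the predicates.
#'
#' @param samples cohort sample data.frame.
#' @param subgroupPredicate,eventPredicate logical-vector functions of the
#'   sample data.frame.
#' @return a single fraction in [0, 1].
#' @export
incidence <- function(samples, subgroupPredicate, eventPredicate) {
  if (!nrow(samples))
    stop("usage error: empty sample list", call. = FALSE)
  samples <- samples[samples$diagnosis != "remission", , drop = FALSE]
  sub <- subgroupPredicate(samples)
  if (!any(sub))
    stop("undefined result: empty subgroup", call. = FALSE)
  ev <- eventPredicate(samples)
  sum(ev & sub) / sum(sub)
}
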