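## Exact Mann-Whitney test and engraftment summaries for the in-vivo layer.

#' Exact Mann-Whitney U test (two-sided)
#'
#' U is the number of (b, a) pairs with b > a plus half the tied pairs,
#' computed via midranks. For small samples (both groups <= \code{exactMax})
#' the two-sided p-value is exact: all choose(n1 + n2, n1) assignments of
#' the pooled (tied) values to groups are enumerated and
#' \code{p = P(U <= min(u, n1*n2 - u)) + P(U >= max(u, n1*n2 - u))}, capped
#' at 1. Ties are handled exactly because the permutation distribution is
#' built from the observed midranks. Larger inputs fall back to the normal
#' approximation with tie correction and continuity correction, flagged in
#' the method string.
#'
#' @param a,b numeric vectors (non-empty). \code{a} is the reference group;
#'   U counts how often \code{b} exceeds \code{a}.
#' @param exactMax largest per-group size for exact enumeration (default 10).
#' @return list with statistic (U), p.value, method, n1, n2.
#' @examples
#' wt <- c(0.07, 0.11, 0.09, 0, 3.1, 0.43)
#' mut <- c(24.7, 30.9, 74.3, 24.70, 1.66, 22.80)
#' mannWhitneyExact(wt, mut)  # U = 35, p = 4/924
#' @export
mannWhitneyExact <- function(a, b, exactMax = 10) {
  if (!length(a) || !length(b))
    stop("usage error: both groups must be non-empty", call. = FALSE)
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))  # midranks
  u <- sum(r[(n1 + 1):n]) - n2 * (n2 + 1) / 2
  if (n1 <= exactMax && n2 <= exactMax) {
    ## permutation distribution of U over all group-label assignments
    idx <- combn(n, n2)
    us <- colSums(matrix(r[idx], nrow = n2)) - n2 * (n2 + 1) / 2
    lo <- min(u, n1 * n2 - u); hi <- max(u, n1 * n2 - u)
    p <- (sum(us <= lo) + sum(us >= hi)) / ncol(idx)
    return(list(statistic = u, p.value = min(1, p),
                method = "mann_whitney_exact", n1 = n1, n2 = n2))
  }
  mu <- n1 * n2 / 2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 == 0) {
    return(list(statistic = u, p.value = 1,
                method = "mann_whitney_normal_approx", n1 = n1, n2 = n2))
  }
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(statistic = u, p.value = min(1, 2 * pnorm(-abs(z))),
       method = "mann_whitney_normal_approx", n1 = n1, n2 = n2)
}

#' Per-group engraftment summary
#'
#' A mouse counts as engrafted iff its percent engraftment strictly exceeds
#' the threshold (default > 1\%); the mean is taken over all mice in the
#' group, engrafted or not.
#'
#' @param records data.frame with columns group and percent_engraftment.
#' @param thresholdPercent engraftment threshold in percent (default 1).
#' @return data.frame with one row per group: group, n, n_engrafted,
#'   fraction_engrafted, mean_percent.
#' @export
engraftmentSummary <- function(records, thresholdPercent = 1.0) {
  if (!nrow(records))
    stop("usage error: empty engraftment table", call. = FALSE)
  out <- do.call(rbind, lapply(split(records, records$group), function(g) {
    eng <- sum(g$percent_engraftment > thresholdPercent)
    data.frame(group = g$group[1], n = nrow(g), n_engrafted = eng,
               fraction_engrafted = eng / nrow(g),
               mean_percent = mean(g$percent_engraftment),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pool engraftment arms into two comparison groups
#'
#' Maps fine-grained vector arms (e.g. the two WT histone arms and the two
#' mutant arms) onto pooled labels for the group comparison.
#'
#' @param records engraftment data.frame.
#' @param pooling named character vector mapping original group labels to
#'   pooled labels.
#' @return the records with group replaced by the pooled label.
#' @export
poolEngraftmentGroups <- function(records, pooling) {
  unknown <- setdiff(unique(records$group), names(pooling))
  if (length(unknown))
    stop(sprintf("usage error: no pooling defined for group(s) %s",
                 paste(sQuote(unknown), collapse = ", ")), call. = FALSE)
  records$group <- unname(pooling[records$group])
  records
}
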