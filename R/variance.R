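#' Inter-individual methylation variance of regions
#'
#' Each region's normalized signal per sample is expressed as a log2 ratio to
#' the across-sample mean (the mean includes the sample itself by default),
#' and the standard deviation of those ratios (denominator n - 1) is the
#' region's methylation-variance metric.
#'
#' @param region_means Regions x samples matrix of normalized mean signal
#'   (rownames = region ids); at least 3 samples.
#' @param offset Depth offset added to both numerator and reference before
#'   the ratio (default 0.1).
#' @param exclusive If `TRUE`, each sample is compared to the mean of the
#'   *other* samples instead of the inclusive mean.
#' @return Data frame with `region` and `sd`; the per-sample log2 ratios are
#'   attached as attribute `"log2_ratios"`.
#' @export
region_variance <- function(region_means, offset = 0.1, exclusive = FALSE) {
  region_means <- as.matrix(region_means)
  n <- ncol(region_means)
  if (n < 3L) stop("region variance needs >= 3 samples")
  if (exclusive) {
    tot <- rowSums(region_means)
    ref <- (tot - region_means) / (n - 1)
  } else {
    ref <- matrix(rowMeans(region_means), nrow(region_means), n)
  }
  ratios <- log2((region_means + offset) / (ref + offset))
  sds <- apply(ratios, 1L, stats::sd)
  ids <- rownames(region_means)
  if (is.null(ids)) ids <- sprintf("region_%d", seq_len(nrow(region_means)))
  out <- data.frame(region = ids, sd = sds, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "log2_ratios") <- ratios
  out
}

#' Rank-sum comparison of two variance distributions
#'
#' Two-sided Wilcoxon/Mann-Whitney rank-sum test, used to compare the
#' methylation-variance metric of candidate individual-specific DMR regions
#' against the invariant MAP-region background. Exact when the combined
#' sample size is at most 20 and there are no ties; otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `statistic` (Mann-Whitney U for `x`) and `p_value`.
#' @export
variance_ranksum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both groups must be non-empty")
  exact <- (length(x) + length(y)) <= 20L &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
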