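# Sample-level sanity checks: hierarchical clustering and PCA of MAP-region
# mean signal.

#' Hierarchically cluster samples on region means
#'
#' Agglomerative clustering on Euclidean distances between the samples'
#' region-mean vectors (complete linkage by default, the base-R default).
#'
#' @param region_means Regions x samples numeric matrix.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return List with `hclust` (the tree), `dist` (the
#'   `sample_distance_matrix`) and `newick` (the tree serialized as newick).
#' @export
cluster_samples <- function(region_means, linkage = "complete") {
  m <- as.matrix(region_means)
  if (ncol(m) < 2L) stop("clustering needs >= 2 samples")
  if (anyNA(m)) stop("region means contain NA/NaN")
  d <- stats::dist(t(m))
  stopifnot(all(d >= 0))
  hc <- stats::hclust(d, method = linkage)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, dist = d, newick = nwk)
}

#' Principal component analysis of samples
#'
#' Centered SVD of the samples' region-mean vectors. A lower signal floor is
#' applied before decomposition and sex chromosomes (`chrX`, `chrY`) can be
#' dropped so dosage does not dominate the leading component.
#'
#' @param region_means Regions x samples numeric matrix.
#' @param chrom Optional chromosome of each region (for sex-chromosome
#'   removal).
#' @param min_depth Lower floor applied to all values before PCA.
#' @param drop_sex_chroms Drop regions on chrX/chrY when `chrom` is given.
#' @param n_components Number of leading components returned.
#' @return List with `scores` (samples x components), `explained` (fraction
#'   of variance per returned component) and `prcomp` (the full fit).
#' @export
pca_samples <- function(region_means, chrom = NULL, min_depth = 0.1,
                        drop_sex_chroms = TRUE, n_components = 3L) {
  m <- as.matrix(region_means)
  if (ncol(m) < 3L) stop("PCA sanity check needs >= 3 samples")
  if (!is.null(chrom) && drop_sex_chroms) {
    keep <- !(chrom %in% c("chrX", "chrY", "X", "Y"))
    m <- m[keep, , drop = FALSE]
  }
  m <- pmax(m, min_depth)
  if (all(apply(m, 1L, stats::var) == 0))
    stop("matrix is constant; no variance to decompose")
  pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       explained = ev[seq_len(k)] / sum(ev),
       prcomp = pc)
}

#' Mean signal per region
#'
#' Collapses a normalized window matrix to MAP-region means (the input to
#' clustering, PCA and the variance metric).
#'
#' @param wm A `window_matrix` (normalized values are used when present,
#'   otherwise raw depth).
#' @return Regions x samples matrix with region ids as rownames; attribute
#'   `"chrom"` carries each region's chromosome.
#' @export
region_mean_matrix <- function(wm) {
  v <- if (wm$normalized) wm$values else wm$depth
  # weight windows by width so the region mean is the true per-base mean
  w <- wm$windows$end - wm$windows$start
  num <- rowsum(v * w, wm$windows$region_id)
  den <- rowsum(w, wm$windows$region_id)
  m <- num / as.vector(den)
  chrom <- vapply(split(wm$windows$chrom, wm$windows$region_id),
                  `[[`, "", 1L)
  attr(m, "chrom") <- chrom[rownames(m)]
  m
}
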