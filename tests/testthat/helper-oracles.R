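# Independent brute-force oracles. These re-derive expected results by the
# most literal route available (per-base scans, exhaustive enumeration,
# closed forms) and stay deliberately separate from the package's
# implementations.

# per-base peak scanner: walk the depth vector, collect maximal qualifying
# runs, bridge gaps between them, apply the length filter last
bf_find_peaks <- function(depth, min_depth, min_length, max_gap) {
  qualifying <- depth >= min_depth
  runs <- list()
  i <- 1L
  n <- length(depth)
  while (i <= n) {
    if (qualifying[i]) {
      j <- i
      while (j < n && qualifying[j + 1L]) j <- j + 1L
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(runs)) return(data.frame(start = numeric(0), end = numeric(0)))
  merged <- list(runs[[1L]])
  for (r in runs[-1L]) {
    last <- merged[[length(merged)]]
    if (r[1L] - last[2L] - 1L <= max_gap) {
      merged[[length(merged)]] <- c(last[1L], r[2L])
    } else merged[[length(merged) + 1L]] <- r
  }
  keep <- Filter(function(r) r[2L] - r[1L] + 1L >= min_length, merged)
  data.frame(start = vapply(keep, `[[`, 0, 1L) - 1,
             end = vapply(keep, `[[`, 0, 2L))
}

# literal step-up definition: adj_i = min over j with rank >= rank(i) of
# m * p_(j) / j, capped at 1 (O(n^2) double loop)
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  r <- integer(m); r[o] <- seq_len(m)
  sorted <- p[o]
  vapply(seq_len(m), function(i) {
    min(1, min(m * sorted[r[i]:m] / (r[i]:m)))
  }, numeric(1))
}

# exhaustive knitting oracle: consider every contiguous run of significant
# same-direction windows, keep runs whose consecutive spacings are all
# within span and that have >= min_windows members, then keep only maximal
# runs (not contained in a longer valid run)
bf_knit <- function(windows, alpha, span, min_windows, anchor = "start") {
  sig <- windows[windows$adj_p < alpha, , drop = FALSE]
  out <- list()
  for (key in unique(paste(sig$chrom, sig$direction))) {
    s <- sig[paste(sig$chrom, sig$direction) == key, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    n <- nrow(s)
    valid <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in i:n) {
      if (j - i + 1L < min_windows) next
      gaps <- if (anchor == "start") diff(s$start[i:j]) else
        s$start[(i + 1):j] - s$end[i:(j - 1)]
      if (j == i || all(gaps <= span)) valid[i, j] <- TRUE
    }
    for (i in seq_len(n)) for (j in i:n) {
      if (!valid[i, j]) next
      # maximal: no valid extension left or right
      ext_l <- i > 1L && valid[i - 1L, j]
      ext_r <- j < n && valid[i, j + 1L]
      if (ext_l || ext_r) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = s$chrom[i], start = s$start[i], end = s$end[j],
        direction = s$direction[i], n_sig_windows = j - i + 1L,
        min_adj_p = min(s$adj_p[i:j]), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      n_sig_windows = integer(0), min_adj_p = numeric(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# exact two-sided rank-sum p-value by enumerating every assignment of the
# pooled observations to the two groups
bf_ranksum_exact <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  m <- length(x)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(length(pooled), m)
  u_all <- apply(idx, 2L, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  mu <- m * (length(y)) / 2
  p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
  list(u = u_obs, p = p)
}

# column-rank -> row-mean-of-sorted-values quantile normalization with tied
# ranks averaged
bf_quantile_normalize <- function(m) {
  sorted <- apply(m, 2L, sort)
  ref <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    rk <- rank(m[, j], ties.method = "average")
    lo <- ref[floor(rk)]
    hi <- ref[ceiling(rk)]
    out[, j] <- (lo + hi) / 2
  }
  out
}

# brute-force complete/average/single-linkage agglomeration returning the
# merge heights and member sets in merge order
bf_agglomerate <- function(points, linkage = "complete") {
  clusters <- as.list(seq_along(points))
  heights <- numeric(0)
  members <- list()
  cluster_dist <- function(a, b) {
    d <- abs(outer(points[a], points[b], "-"))
    switch(linkage, complete = max(d), single = min(d), average = mean(d))
  }
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- cluster_dist(clusters[[i]], clusters[[j]])
      if (d < bd) { bd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    members[[length(members) + 1L]] <-
      sort(c(clusters[[best[1L]]], clusters[[best[2L]]]))
    clusters[[best[1L]]] <- members[[length(members)]]
    clusters <- clusters[-best[2L]]
  }
  list(heights = heights, members = members)
}
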