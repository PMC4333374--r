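#' Tile MAP-regions into abutting windows
#'
#' Each region is tiled left-to-right with `width`-bp abutting windows; a
#' terminal remainder window (< `width` bp) is retained and flagged, so every
#' base of every region is covered exactly once.
#'
#' @param regions Sorted, disjoint interval data frame with an `id` column.
#' @param width Window width (bp), 50 by default.
#' @return Window data frame: chrom, start, end, region_id, window_id,
#'   is_remainder.
#' @export
tile_windows <- function(regions, width = 50L) {
  if (nrow(regions) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), region_id = character(),
                      window_id = character(), is_remainder = logical(),
                      stringsAsFactors = FALSE))
  if (is.null(regions$id)) regions$id <- sprintf("region_%d", seq_len(nrow(regions)))
  n_win <- ceiling((regions$end - regions$start) / width)
  ri <- rep.int(seq_len(nrow(regions)), n_win)
  k <- unlist(lapply(n_win, seq_len)) - 1L
  start <- regions$start[ri] + k * width
  end <- pmin(start + width, regions$end[ri])
  data.frame(chrom = regions$chrom[ri], start = start, end = end,
             region_id = regions$id[ri],
             window_id = paste0(regions$chrom[ri], ":", start, "-", end),
             is_remainder = (end - start) < width,
             stringsAsFactors = FALSE)
}

#' Build a windows-by-samples mean-depth matrix
#'
#' @param tracks Named list of `coverage_track`s, one per sample.
#' @param windows Window data frame from [tile_windows()].
#' @return A `window_matrix`: list with `windows`, `samples`, `depth`
#'   (windows x samples mean read depth) and `normalized = FALSE`.
#' @export
window_depth_matrix <- function(tracks, windows) {
  if (is.null(names(tracks)) || anyDuplicated(names(tracks)))
    stop("tracks must be a uniquely named list (one per sample)")
  depth <- vapply(tracks, mean_depth, numeric(nrow(windows)),
                  windows = windows)
  if (nrow(windows) == 1L) depth <- matrix(depth, nrow = 1L,
                                           dimnames = list(NULL, names(tracks)))
  rownames(depth) <- windows$window_id
  structure(list(windows = windows, samples = names(tracks), depth = depth,
                 values = NULL, normalized = FALSE, offset = NULL,
                 scale = NULL),
            class = "window_matrix")
}

#' @export
print.window_matrix <- function(x, ...) {
  cat("<window_matrix> ", nrow(x$windows), " windows x ",
      length(x$samples), " samples",
      if (x$normalized) paste0(" (normalized, offset ", x$offset,
                               ", scale ", x$scale, ")") else " (raw depth)",
      "\n", sep = "")
  invisible(x)
}

#' Normalize a window matrix against the average-depth reference
#'
#' The normalization pipeline: a nominal depth offset (default 0.1, guarding
#' against division by zero) is added to every mean depth; the per-window
#' across-sample average of the offset depths is the common reference; each
#' sample is expressed as a ratio to that reference; the ratio matrix is
#' quantile normalized across samples (ties averaged), eliminating residual
#' sequencing-depth variability. After normalization every sample's sorted
#' value vector is identical.
#'
#' @param wm A raw `window_matrix`.
#' @param offset Depth offset added before ratio formation (> 0).
#' @param log2_scale If `TRUE`, quantile-normalize log2 ratios instead of
#'   ratios (sensitivity analysis; downstream modelling then skips its own
#'   log transform).
#' @return The `window_matrix` with normalized `values` and
#'   `normalized = TRUE`.
#' @export
normalize_windows <- function(wm, offset = 0.1, log2_scale = FALSE) {
  stopifnot(inherits(wm, "window_matrix"))
  if (wm$normalized) stop("matrix is already normalized")
  if (offset <= 0) stop("offset must be > 0")
  if (length(wm$samples) < 2L)
    stop("normalization needs >= 2 samples (the average-depth reference is ",
         "undefined as a contrast for a single sample)")
  d <- wm$depth + offset
  ref <- rowMeans(d)
  ratio <- d / ref
  if (log2_scale) ratio <- log2(ratio)
  norm <- limma::normalizeQuantiles(ratio, ties = TRUE)
  dimnames(norm) <- dimnames(wm$depth)
  wm$values <- norm
  wm$normalized <- TRUE
  wm$offset <- offset
  wm$scale <- if (log2_scale) "log2" else "ratio"
  wm
}
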