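# Genomic intervals are plain data.frames with chrom/start/end columns in
# 0-based half-open (BED) coordinates. All internal code uses this convention;
# conversion to other conventions (GFF 1-based inclusive, IRanges 1-based
# closed) happens only at format boundaries.

#' Construct a genomic-interval data frame
#'
#' Intervals are represented throughout the package as data frames with
#' `chrom`, `start` and `end` columns in 0-based half-open (BED) coordinates.
#' This constructor validates the coordinates.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector of 0-based start positions.
#' @param end Integer vector of end positions (exclusive).
#' @param ... Further columns recycled to the same length (e.g. `id`,
#'   `strand`).
#' @return A data frame with at least `chrom`, `start`, `end`.
#' @export
intervals <- function(chrom, start, end, ...) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  data.frame(chrom = as.character(chrom), start = start, end = end, ...,
             stringsAsFactors = FALSE)
}

# sort by chrom then start (stable)
sort_intervals <- function(bed) {
  if (nrow(bed) == 0L) return(bed)
  bed[order(bed$chrom, bed$start, bed$end), , drop = FALSE]
}

# data.frame (0-based half-open) -> IRanges (1-based closed), one chromosome
as_iranges <- function(bed) {
  IRanges::IRanges(start = bed$start + 1L, end = bed$end)
}

#' Merge (union) a set of intervals
#'
#' Computes the union of possibly overlapping intervals per chromosome, the
#' first step of MAP-region construction when peak sets from many samples are
#' pooled.
#'
#' @param bed Interval data frame (`chrom`, `start`, `end`).
#' @param min_gap Merge intervals separated by less than `min_gap` bases
#'   (default 0: only touching/overlapping intervals merge).
#' @return Sorted, disjoint interval data frame.
#' @export
merge_intervals <- function(bed, min_gap = 0L) {
  if (nrow(bed) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  pieces <- lapply(split(bed, bed$chrom), function(b) {
    r <- IRanges::reduce(as_iranges(b), min.gapwidth = min_gap + 1L)
    data.frame(chrom = b$chrom[1L], start = IRanges::start(r) - 1,
               end = as.numeric(IRanges::end(r)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  sort_intervals(out)
}

#' Test intervals for overlap with a subject set
#'
#' @param query,subject Interval data frames.
#' @return Logical vector, one per `query` row: does it overlap (>= 1 bp) any
#'   subject interval?
#' @export
overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  hit <- rep(FALSE, nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    sub <- subject[subject$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0L) next
    ov <- IRanges::overlapsAny(as_iranges(query[qi, , drop = FALSE]),
                               as_iranges(sub))
    hit[qi] <- ov
  }
  hit
}

# midpoint (numeric, may be half-integral)
interval_midpoints <- function(bed) (bed$start + bed$end) / 2

# subtract subject intervals from query intervals (used by the trimming
# repeat policy)
setdiff_intervals <- function(query, subject) {
  if (nrow(query) == 0L) return(query)
  pieces <- lapply(split(query, query$chrom), function(q) {
    sub <- subject[subject$chrom == q$chrom[1L], , drop = FALSE]
    if (nrow(sub) == 0L) return(q[c("chrom", "start", "end")])
    d <- IRanges::setdiff(as_iranges(q), as_iranges(sub))
    if (length(d) == 0L) return(NULL)
    data.frame(chrom = q$chrom[1L], start = IRanges::start(d) - 1,
               end = as.numeric(IRanges::end(d)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  rownames(out) <- NULL
  sort_intervals(out)
}
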