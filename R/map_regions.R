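#' Peak-finding parameters
#'
#' Defaults are the low-stringency settings used for MAP-seq enrichment:
#' depth four reads, minimum length 90 bp, maximum bridged gap 50 bp.
#'
#' @param min_depth Minimum read depth for a qualifying run.
#' @param min_length Minimum peak length (bp), applied after gap bridging.
#' @param max_gap Maximum sub-threshold gap (bp) bridged between qualifying
#'   runs.
#' @return A `peak_params` list.
#' @export
peak_params <- function(min_depth = 4, min_length = 90L, max_gap = 50L) {
  if (min_depth <= 0 || min_length < 1 || max_gap <= 0)
    stop("peak parameters must be strictly positive (min_length >= 1)")
  structure(list(min_depth = min_depth, min_length = as.integer(min_length),
                 max_gap = as.integer(max_gap)), class = "peak_params")
}

#' Find coverage peaks in one sample
#'
#' A peak is a maximal interval where depth meets `min_depth`, after bridging
#' sub-threshold gaps of at most `max_gap` bp between qualifying runs;
#' bridged intervals shorter than `min_length` are discarded. Gaps are only
#' bridged between runs that each meet the depth threshold, and the length
#' test is applied after bridging.
#'
#' @param track A `coverage_track`.
#' @param params A [peak_params()].
#' @return Sorted, non-overlapping interval data frame of peaks.
#' @export
find_peaks <- function(track, params = peak_params()) {
  out <- list()
  for (ch in names(track$rle)) {
    r <- track$rle[[ch]]
    rl <- S4Vectors::runLength(r)
    rv <- S4Vectors::runValue(r)
    ends <- cumsum(rl)               # 1-based inclusive run ends
    starts <- ends - rl + 1L
    ok <- rv >= params$min_depth
    if (!any(ok)) next
    qs <- starts[ok]; qe <- ends[ok]
    # bridge gaps <= max_gap between successive qualifying runs
    if (length(qs) > 1L) {
      gap <- qs[-1L] - qe[-length(qe)] - 1L
      grp <- cumsum(c(1L, as.integer(gap > params$max_gap)))
    } else grp <- 1L
    ms <- vapply(split(qs, grp), min, numeric(1))
    me <- vapply(split(qe, grp), max, numeric(1))
    keep <- (me - ms + 1L) >= params$min_length
    if (!any(keep)) next
    out[[ch]] <- data.frame(chrom = ch, start = ms[keep] - 1,
                            end = me[keep], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  sort_intervals(res)
}

# CpG (forward-strand CG dinucleotide) count of each interval, from sequence
count_cpgs <- function(bed, sequences) {
  if (nrow(bed) == 0L) return(integer(0))
  missing <- setdiff(unique(bed$chrom), names(sequences))
  if (length(missing))
    stop("chromosome(s) absent from genome FASTA: ",
         paste(missing, collapse = ", "))
  vapply(seq_len(nrow(bed)), function(i) {
    s <- Biostrings::subseq(sequences[[bed$chrom[i]]],
                            bed$start[i] + 1L, bed$end[i])
    Biostrings::countPattern("CG", s)
  }, integer(1))
}

#' Build MAP-regions from per-sample peak sets
#'
#' The analyzable universe: peaks from all samples (plus any published
#' auxiliary peak sets) are union-merged; merged intervals containing
#' repeat-masked sequence are removed entirely (the default policy) or
#' trimmed; survivors are kept only if longer than `min_len` bp and carrying
#' at least `min_cpg` CpGs in the reference sequence.
#'
#' @param peaks_by_sample Named list of per-sample peak interval data frames.
#' @param extra_peak_sets Optional list of additional peak sets to merge in.
#' @param repeats Repeat-mask interval data frame (may be empty).
#' @param sequences Genome as a named [Biostrings::DNAStringSet].
#' @param min_len Strict length filter: regions must be longer than this.
#' @param min_cpg Minimum CpG count.
#' @param repeat_policy `"remove"` drops any interval overlapping a repeat by
#'   >= 1 bp; `"trim"` subtracts the repeat bases instead.
#' @return Data frame of MAP-regions: chrom, start, end, id, length,
#'   cpg_count, n_source_samples, sources (comma-separated contributing
#'   sample ids). Regions are sorted and pairwise disjoint.
#' @export
build_map_regions <- function(peaks_by_sample, extra_peak_sets = list(),
                              repeats = NULL, sequences, min_len = 250L,
                              min_cpg = 2L,
                              repeat_policy = c("remove", "trim")) {
  repeat_policy <- match.arg(repeat_policy)
  all_sets <- c(peaks_by_sample, extra_peak_sets)
  pooled <- do.call(rbind, lapply(all_sets, function(b)
    b[c("chrom", "start", "end")]))
  if (is.null(pooled) || nrow(pooled) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), id = character(), length = numeric(),
                      cpg_count = integer(), n_source_samples = integer(),
                      sources = character(), stringsAsFactors = FALSE))
  merged <- merge_intervals(pooled)
  missing <- setdiff(unique(merged$chrom), names(sequences))
  if (length(missing))
    stop("chromosome(s) present in peaks but absent from FASTA: ",
         paste(missing, collapse = ", "))
  if (!is.null(repeats) && nrow(repeats)) {
    if (repeat_policy == "remove") {
      merged <- merged[!overlaps_any(merged, repeats), , drop = FALSE]
    } else {
      merged <- setdiff_intervals(merged, repeats)
    }
  }
  if (nrow(merged) == 0L)
    return(build_map_regions(list(), sequences = sequences))
  merged$length <- merged$end - merged$start
  merged$cpg_count <- count_cpgs(merged, sequences)
  keep <- merged$length > min_len & merged$cpg_count >= min_cpg
  reg <- merged[keep, , drop = FALSE]
  if (nrow(reg)) {
    reg$id <- sprintf("mapr_%05d", seq_len(nrow(reg)))
    # which samples contributed a peak to each region
    src <- vector("list", nrow(reg))
    for (s in names(peaks_by_sample)) {
      hit <- overlaps_any(reg, peaks_by_sample[[s]])
      for (i in which(hit)) src[[i]] <- c(src[[i]], s)
    }
    reg$n_source_samples <- lengths(src)
    reg$sources <- vapply(src, paste, "", collapse = ",")
  } else {
    reg$id <- character(0)
    reg$n_source_samples <- integer(0)
    reg$sources <- character(0)
  }
  rownames(reg) <- NULL
  reg[c("chrom", "start", "end", "id", "length", "cpg_count",
        "n_source_samples", "sources")]
}
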