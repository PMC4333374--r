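# DMR characterization: base composition, annotation hierarchy, CGI
# co-localization and chromosome-arm distribution.

#' Sequence composition statistics
#'
#' For each sequence: G+C fraction, CpG dinucleotides per 100 bp and the CpG
#' observed/expected ratio `#CG * len / (#C * #G)`. `N` bases are excluded
#' from all denominators. Islands of methylation-resistant promoter sequence
#' typically show o/e near 1, the CpG-depleted bulk genome near 0.2.
#'
#' @param seqs Character vector or [Biostrings::DNAStringSet] of sequences
#'   over A, C, G, T, N.
#' @return Data frame with `gc_fraction`, `cpg_per_100bp`, `cpg_oe` (o/e is
#'   `NA` when the sequence has no C or no G).
#' @export
seq_stats <- function(seqs) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::alphabetFrequency(seqs)
  nC <- freq[, "C"]; nG <- freq[, "G"]
  len <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  ncg <- Biostrings::vcountPattern("CG", seqs)
  gc <- ifelse(len > 0, (nC + nG) / len, NA_real_)
  dens <- ifelse(len > 0, 100 * ncg / len, NA_real_)
  oe <- ifelse(nC > 0 & nG > 0, ncg * len / (nC * nG), NA_real_)
  data.frame(gc_fraction = gc, cpg_per_100bp = dens, cpg_oe = oe)
}

#' Sequence statistics of intervals against a genome
#'
#' @param bed Interval data frame.
#' @param sequences Genome [Biostrings::DNAStringSet].
#' @return [seq_stats()] data frame, one row per interval.
#' @export
interval_seq_stats <- function(bed, sequences) {
  if (nrow(bed) == 0L)
    return(data.frame(gc_fraction = numeric(0), cpg_per_100bp = numeric(0),
                      cpg_oe = numeric(0)))
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(bed)), function(i)
    as.character(Biostrings::subseq(sequences[[bed$chrom[i]]],
                                    bed$start[i] + 1L, bed$end[i])),
    ""))
  seq_stats(seqs)
}

#' Classify intervals against the genomic-annotation hierarchy
#'
#' Each interval receives exactly one category, the first match in the fixed
#' precedence order: (i) TSS (within +/-500 bp of a transcription start
#' site), (ii) exonic, (iii) intronic, (iv) upstream (501-2000 bp 5' of a
#' TSS on the gene's strand) and (v) intergenic. An interval near several
#' genes takes the highest-precedence category over any of them.
#'
#' @param bed Interval data frame (e.g. DMRs).
#' @param annotation A `gene_annotation` (see [gene_annotation()] /
#'   [read_gff()]).
#' @param tss_flank Half-width of the TSS window (bp).
#' @param upstream_range Distances 5' of the TSS defining the upstream
#'   category.
#' @return Factor of categories (`TSS`, `exonic`, `intronic`, `upstream`,
#'   `intergenic`), one per interval.
#' @export
classify_annotation <- function(bed, annotation, tss_flank = 500L,
                                upstream_range = c(501L, 2000L)) {
  stopifnot(inherits(annotation, "gene_annotation"))
  genes <- annotation$genes
  exons <- annotation$exons
  lv <- c("TSS", "exonic", "intronic", "upstream", "intergenic")
  if (nrow(bed) == 0L) return(factor(character(0), levels = lv))
  # TSS base (0-based): first transcribed base on the gene's strand
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  tss_iv <- data.frame(chrom = genes$chrom,
                       start = pmax(0, tss - tss_flank),
                       end = tss + tss_flank + 1)
  up_iv <- data.frame(chrom = genes$chrom,
                      start = pmax(0, ifelse(genes$strand == "+",
                                             tss - upstream_range[2L],
                                             tss + upstream_range[1L])),
                      end = ifelse(genes$strand == "+",
                                   tss - upstream_range[1L] + 1,
                                   tss + upstream_range[2L] + 1))
  intron_iv <- setdiff_intervals(genes[c("chrom", "start", "end")],
                                 exons[c("chrom", "start", "end")])
  cat <- rep("intergenic", nrow(bed))
  cat[overlaps_any(bed, up_iv)] <- "upstream"
  cat[overlaps_any(bed, intron_iv)] <- "intronic"
  cat[overlaps_any(bed, exons[c("chrom", "start", "end")])] <- "exonic"
  cat[overlaps_any(bed, tss_iv)] <- "TSS"
  factor(cat, levels = lv)
}

#' CGI co-localization profile of DMRs
#'
#' For every DMR whose midpoint lies within `flank` bp of the nearest CpG
#' island center, records the signed midpoint-to-center distance (negative =
#' DMR left of the island center). Offsets are also binned into a profile;
#' if per-DMR levels are supplied (e.g. mean log2 differential methylation),
#' a binned mean-level profile is returned as well.
#'
#' @param dmrs DMR interval data frame.
#' @param cgis CGI interval data frame.
#' @param flank Half-width of the profile (bp, default 5000).
#' @param n_bins Number of profile bins across `[-flank, flank]`.
#' @param levels Optional numeric per-DMR level (same order as `dmrs`).
#' @return List with `offsets` (data frame: dmr index, cgi index, offset,
#'   level) and `profile` (data frame: bin midpoint, count, mean level).
#' @export
cgi_colocalization <- function(dmrs, cgis, flank = 5000L, n_bins = 50L,
                               levels = NULL) {
  mid_d <- interval_midpoints(dmrs)
  mid_c <- interval_midpoints(cgis)
  rows <- list()
  for (i in seq_len(nrow(dmrs))) {
    same <- which(cgis$chrom == dmrs$chrom[i])
    if (!length(same)) next
    d <- mid_d[i] - mid_c[same]
    j <- same[which.min(abs(d))]
    off <- mid_d[i] - mid_c[j]
    if (abs(off) > flank) next
    rows[[length(rows) + 1L]] <- data.frame(
      dmr = i, cgi = j, offset = off,
      level = if (is.null(levels)) NA_real_ else levels[i])
  }
  offsets <- if (length(rows)) do.call(rbind, rows) else
    data.frame(dmr = integer(0), cgi = integer(0), offset = numeric(0),
               level = numeric(0))
  breaks <- seq(-flank, flank, length.out = n_bins + 1L)
  bin <- cut(offsets$offset, breaks, include.lowest = TRUE)
  mean_level <- rep(NA_real_, n_bins)
  if (nrow(offsets)) {
    agg <- tapply(offsets$level, bin, mean)
    mean_level <- as.numeric(agg)
  }
  profile <- data.frame(
    mid = (breaks[-1L] + breaks[-length(breaks)]) / 2,
    count = as.integer(table(bin)),
    mean_level = mean_level)
  list(offsets = offsets, profile = profile)
}

#' Chromosome-arm percentile distribution of DMRs
#'
#' Each arm is scaled to 100 percentile bins running from the
#' centromere-proximal end (percentile 1) to the telomere (percentile 100);
#' the reported value per bin is the number of DMR midpoints divided by the
#' number of MAP-region midpoints falling in it. Bins without MAP-regions
#' are `NA`, never infinite.
#'
#' @param dmrs,map_regions Interval data frames.
#' @param arms Optional arm definitions: data frame with chrom, start, end,
#'   `centromeric_end` (`"start"` or `"end"`). Default: one arm per
#'   chromosome spanning the observed MAP-region extent, centromere at the
#'   start.
#' @return Data frame with `percentile`, `n_dmr`, `n_map`, `ratio`
#'   (aggregated over arms).
#' @export
arm_percentile_distribution <- function(dmrs, map_regions, arms = NULL) {
  if (is.null(arms)) {
    sp <- split(map_regions, map_regions$chrom)
    arms <- do.call(rbind, lapply(sp, function(b)
      data.frame(chrom = b$chrom[1L], start = 0, end = max(b$end),
                 centromeric_end = "start", stringsAsFactors = FALSE)))
  }
  pct_of <- function(bed) {
    mids <- interval_midpoints(bed)
    out <- rep(NA_integer_, nrow(bed))
    for (i in seq_len(nrow(arms))) {
      a <- arms[i, ]
      inside <- bed$chrom == a$chrom & mids >= a$start & mids < a$end
      frac <- (mids[inside] - a$start) / (a$end - a$start)
      if (a$centromeric_end == "end") frac <- 1 - frac
      out[inside] <- pmin(100L, floor(frac * 100) + 1L)
    }
    out
  }
  pd <- pct_of(dmrs); pm <- pct_of(map_regions)
  n_dmr <- tabulate(pd[!is.na(pd)], nbins = 100L)
  n_map <- tabulate(pm[!is.na(pm)], nbins = 100L)
  data.frame(percentile = 1:100, n_dmr = n_dmr, n_map = n_map,
             ratio = ifelse(n_map > 0, n_dmr / n_map, NA_real_))
}
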