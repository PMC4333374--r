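#' mapdmr: DMR calling for MBD-affinity-purification sequencing
#'
#' Methylated-DNA affinity purification followed by sequencing (MAP-seq /
#' MBD-seq) yields read depth proportional to local methyl-CpG density. This
#' package identifies differentially methylated regions from such coverage:
#' peaks per sample are merged into repeat-free, CpG-bearing MAP-regions;
#' regions are tiled into abutting 50-bp windows whose mean depths are
#' ratio-to-reference quantile normalized; moderated window statistics with
#' Benjamini-Hochberg correction flag differential windows; and runs of at
#' least three same-direction significant windows within 500 bp are knitted
#' into DMRs. [mapseq_dmr()] runs the whole strategy; the stage functions
#' ([find_peaks()], [build_map_regions()], [tile_windows()],
#' [normalize_windows()], [dmr_fit()], [knit_dmrs()]) are exported
#' individually, as are characterization, variance-metric, clustering and
#' simulation tools.
#'
#' @keywords internal
"_PACKAGE"

#' Run the complete DMR-calling strategy
#'
#' Orchestrates every stage from per-sample coverage to knitted DMRs:
#' peak finding, MAP-region construction (merge, repeat exclusion, length and
#' CpG filters), 50-bp window tiling, mean-depth matrix, offset +
#' ratio-to-reference + quantile normalization, moderated window models, BH
#' correction and knitting.
#'
#' @param tracks Named list of `coverage_track`s (one per sample).
#' @param sequences Genome as a named [Biostrings::DNAStringSet].
#' @param sample_sheet Data frame with `sample_id` and the biological
#'   variables.
#' @param variable,contrast Passed to [design_spec()].
#' @param repeats Repeat-mask interval data frame (optional).
#' @param extra_peak_sets Additional peak sets merged into the MAP-region
#'   universe (optional).
#' @param peaks Peak-finding parameters ([peak_params()]).
#' @param min_region_len,min_region_cpg MAP-region filters (strictly longer
#'   than `min_region_len` bp; at least `min_region_cpg` CpGs).
#' @param window Window width (bp).
#' @param offset Depth offset for normalization.
#' @param alpha,span,min_windows Knitting parameters (BH-adjusted
#'   significance level, chaining span, minimum significant windows).
#' @return An object of class `mapdmr`: list with `map_regions`, `matrix`
#'   (the normalized `window_matrix`), `fit` (the `dmr_fit`), `dmrs` (the
#'   `dmr_set`) and `params`.
#' @export
mapseq_dmr <- function(tracks, sequences, sample_sheet, variable, contrast,
                       repeats = NULL, extra_peak_sets = list(),
                       peaks = peak_params(), min_region_len = 250L,
                       min_region_cpg = 2L, window = 50L, offset = 0.1,
                       alpha = 0.01, span = 500L, min_windows = 3L) {
  peak_sets <- lapply(tracks, find_peaks, params = peaks)
  regions <- build_map_regions(peak_sets, extra_peak_sets = extra_peak_sets,
                               repeats = repeats, sequences = sequences,
                               min_len = min_region_len,
                               min_cpg = min_region_cpg)
  windows <- tile_windows(regions, width = window)
  wm <- window_depth_matrix(tracks, windows)
  wm <- normalize_windows(wm, offset = offset)
  design <- design_spec(sample_sheet, variable, contrast)
  dmrs <- call_dmrs(wm, design, alpha = alpha, span = span,
                    min_windows = min_windows)
  structure(list(map_regions = regions, matrix = wm,
                 fit = attr(dmrs, "fit"), dmrs = dmrs,
                 params = list(peaks = peaks,
                               min_region_len = min_region_len,
                               min_region_cpg = min_region_cpg,
                               window = window, offset = offset,
                               alpha = alpha, span = span,
                               min_windows = min_windows)),
            class = "mapdmr")
}

#' @export
print.mapdmr <- function(x, ...) {
  cat("MAP-seq DMR analysis\n")
  cat("  MAP-regions: ", nrow(x$map_regions), " (",
      sum(x$map_regions$length), " bp)\n", sep = "")
  cat("  windows:     ", nrow(x$matrix$windows), " x ",
      length(x$matrix$samples), " samples\n", sep = "")
  cat("  contrast:    ", x$fit$design$variable, ": ",
      x$fit$design$contrast[1L], " vs ", x$fit$design$contrast[2L],
      "\n", sep = "")
  cat("  DMRs:        ", nrow(x$dmrs), " (",
      sum(x$dmrs$direction == "hyper"), " hyper, ",
      sum(x$dmrs$direction == "hypo"), " hypo) at adj P < ",
      x$params$alpha, "\n", sep = "")
  invisible(x)
}

#' @export
summary.mapdmr <- function(object, ...) {
  print(object)
  summary(object$fit, alpha = object$params$alpha)
}

#' @export
coef.mapdmr <- function(object, ...) coef(object$fit)

#' @export
residuals.mapdmr <- function(object, ...) residuals(object$fit)

#' @export
plot.mapdmr <- function(x, ...) plot(x$fit, alpha = x$params$alpha, ...)

#' Simulate a complete MAP-seq experiment
#'
#' Convenience wrapper tying the synthetic-genome, methylation-state and
#' coverage generators together at a scale where the pipeline yields roughly
#' `n_regions` MAP-regions: the genome carries `n_regions /
#' frac_cgi_methylated` CpG islands (in expectation) of which the methylated
#' ones become enrichable domains.
#'
#' @param n_regions Target number of methylated (enrichable) islands.
#' @param sample_sheet Data frame with `sample_id` and biological variables.
#' @param effects List of [effect_spec()], or a function
#'   `function(genome, states)` returning such a list (island ids are only
#'   known once the genome exists, so spike designs are most conveniently
#'   written as functions over [methylated_cgi_ids()]).
#' @param n_chromosomes,bp_per_region Genome geometry.
#' @param frac_cgi_methylated Fraction of islands that are methylated.
#' @param depth_scale,frag_length Coverage model parameters.
#' @param repeat_fraction Repeat-mask fraction.
#' @param seed Master seed for genome, states and coverage.
#' @return List with `genome`, `states`, `tracks`, `truth`, `sample_sheet`.
#' @export
simulate_mapseq_experiment <- function(n_regions, sample_sheet,
                                       effects = list(),
                                       n_chromosomes = 1L,
                                       bp_per_region = 4000,
                                       frac_cgi_methylated = 0.7,
                                       depth_scale = 1,
                                       frag_length = 200L,
                                       repeat_fraction = 0.02,
                                       seed = 1L) {
  chrom_length <- ceiling(n_regions * bp_per_region / n_chromosomes)
  density <- n_regions / frac_cgi_methylated /
    (n_chromosomes * chrom_length / 1e6)
  spec <- synthetic_genome_spec(n_chromosomes = n_chromosomes,
                                chrom_length = chrom_length,
                                cgi_density = density,
                                repeat_fraction = repeat_fraction,
                                seed = seed)
  genome <- make_genome(spec)
  states <- methylation_states(genome,
                               frac_cgi_methylated = frac_cgi_methylated,
                               seed = seed + 1L)
  if (is.function(effects)) effects <- effects(genome, states)
  sim <- simulate_coverage(genome, states, sample_sheet, effects = effects,
                           depth_scale = depth_scale,
                           frag_length = frag_length, seed = seed + 2L)
  list(genome = genome, states = states, tracks = sim$tracks,
       truth = sim$truth, sample_sheet = sample_sheet)
}

#' Ids of methylated (enrichable) islands
#'
#' @param genome A `map_genome`.
#' @param states A `methylation_states`.
#' @param chrom Optionally restrict to one chromosome.
#' @return Character vector of island ids retained by the affinity
#'   purification (i.e. candidates for spiked effects).
#' @export
methylated_cgi_ids <- function(genome, states, chrom = NULL) {
  ids <- states$methylated_cgi
  if (!is.null(chrom))
    ids <- intersect(ids, genome$cgi$id[genome$cgi$chrom %in% chrom])
  ids
}
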