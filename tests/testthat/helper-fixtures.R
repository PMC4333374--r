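# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite runs in minutes.

# a coverage track over one chromosome from a plain depth vector
toy_track <- function(depth, chrom = "chr1") {
  coverage_track(stats::setNames(list(depth), chrom))
}

# random run-structured depth vector (patches of elevated depth on a low
# background), the shape peak finding consumes
random_depth <- function(n, n_patches = 5L, max_depth = 8L,
                         widths = 20:150) {
  d <- sample(0:2, n, replace = TRUE, prob = c(0.7, 0.2, 0.1))
  for (k in seq_len(n_patches)) {
    w <- sample(widths, 1L)
    s <- sample(seq_len(max(1L, n - w)), 1L)
    d[s:(s + w - 1L)] <- d[s:(s + w - 1L)] + sample(2:max_depth, 1L)
  }
  d
}

# sample sheet with a two-level group split
group_sheet <- function(n_a, n_b, var = "group", levels = c("A", "B")) {
  n <- n_a + n_b
  df <- data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                   individual = sprintf("i%02d", seq_len(n)),
                   stringsAsFactors = FALSE)
  df[[var]] <- rep(levels, c(n_a, n_b))
  df
}

# small spiked experiment reused by several tests: n_spike hyper (x2) and
# n_spike hypo (x0.5) islands among ~n_regions enrichable regions
spiked_experiment <- function(n_regions, sheet, n_spike, seed,
                              effect = 2, variable = "group", level = "B") {
  mk <- function(genome, states) {
    ids <- methylated_cgi_ids(genome, states)
    stopifnot(length(ids) >= 2 * n_spike)
    list(effect_spec(variable, level, ids[seq_len(n_spike)], effect),
         effect_spec(variable, level,
                     ids[n_spike + seq_len(n_spike)], 1 / effect))
  }
  simulate_mapseq_experiment(n_regions, sheet, effects = mk, seed = seed)
}

# run the full pipeline on a simulated experiment
run_pipeline <- function(sim, variable, contrast, ...) {
  mapseq_dmr(sim$tracks, sim$genome$sequences, sim$sample_sheet,
             variable, contrast, repeats = sim$genome$repeats, ...)
}

# fraction of truth intervals recovered by a direction-matched DMR, and the
# fraction of called DMRs overlapping no truth interval
score_calls <- function(dmrs, truth) {
  dmrs <- as.data.frame(dmrs)
  sens <- if (nrow(truth) == 0L) NA_real_ else
    mean(vapply(seq_len(nrow(truth)), function(i) {
      any(dmrs$chrom == truth$chrom[i] &
            dmrs$start < truth$end[i] & dmrs$end > truth$start[i] &
            dmrs$direction == truth$direction[i])
    }, logical(1)))
  fdr <- if (nrow(dmrs) == 0L) 0 else
    mean(!overlaps_any(dmrs, truth))
  list(sensitivity = sens, fdr = fdr, n_called = nrow(dmrs))
}

# minimal two-gene annotation on one chromosome for hierarchy tests:
#   geneA: + strand [10000, 16000), exons [10000,11000) and [15000,16000)
#   geneB: - strand [40000, 46000), exons [40000,41000) and [45000,46000)
toy_annotation <- function() {
  genes <- data.frame(chrom = "chr1",
                      start = c(10000, 40000), end = c(16000, 46000),
                      strand = c("+", "-"), id = c("geneA", "geneB"),
                      stringsAsFactors = FALSE)
  exons <- data.frame(chrom = "chr1",
                      start = c(10000, 15000, 40000, 45000),
                      end = c(11000, 16000, 41000, 46000),
                      gene_id = c("geneA", "geneA", "geneB", "geneB"),
                      stringsAsFactors = FALSE)
  gene_annotation(genes, exons)
}
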