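# Synthetic methylome generator. Emulates the signal structure of
# MBD-affinity-purified sequencing: local read depth rises with the density of
# methylated CpGs, CpG islands carry distinct base composition, repeats mask
# part of the genome, and genetic differences between individuals (CpG-loss
# SNPs, CpG-rich insertions) perturb the signal through the sequence channel
# alone.

#' Specification of a synthetic genome
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param cgi_density Expected CpG islands per Mb (Poisson).
#' @param cgi_length_range Length range (bp) of CpG islands, drawn uniformly.
#' @param repeat_fraction Fraction of bases covered by the simulated repeat
#'   mask (0 <= f < 1).
#' @param gc_background,gc_cgi G+C fraction of background sequence and of CpG
#'   islands; islands must be GC-richer than background.
#' @param cpg_depletion Probability that a background CpG dinucleotide is
#'   destroyed (CG -> CA), emulating the CpG depletion of bulk vertebrate
#'   genomes so that CpG o/e is low outside islands.
#' @param seed Integer seed; identical specs give byte-identical genomes.
#' @return A validated `synthetic_genome_spec`.
#' @export
synthetic_genome_spec <- function(n_chromosomes = 1L,
                                  chrom_length = 1e6,
                                  cgi_density = 50,
                                  cgi_length_range = c(400, 1000),
                                  repeat_fraction = 0.05,
                                  gc_background = 0.41,
                                  gc_cgi = 0.65,
                                  cpg_depletion = 0.9,
                                  seed = 1L) {
  if (chrom_length <= 0) stop("chrom_length must be > 0")
  if (repeat_fraction < 0 || repeat_fraction >= 1)
    stop("repeat_fraction must be in [0, 1)")
  if (gc_cgi <= gc_background)
    stop("gc_cgi must exceed gc_background (CGIs are GC-rich by construction)")
  if (max(cgi_length_range) >= chrom_length)
    stop("cgi_length_range exceeds chrom_length")
  if (min(cgi_length_range) <= 0) stop("cgi_length_range must be positive")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 cgi_density = cgi_density,
                 cgi_length_range = cgi_length_range,
                 repeat_fraction = repeat_fraction,
                 gc_background = gc_background,
                 gc_cgi = gc_cgi,
                 cpg_depletion = cpg_depletion,
                 seed = as.integer(seed)),
            class = "synthetic_genome_spec")
}

# place n non-overlapping intervals with the given lengths on [0, chrom_len);
# rejection sampling, deterministic under the active RNG state
place_intervals <- function(n, lengths, chrom_len, max_iter = 200L) {
  if (n == 0L) return(data.frame(start = numeric(0), end = numeric(0)))
  placed_s <- numeric(0); placed_e <- numeric(0)
  need <- n
  for (iter in seq_len(max_iter)) {
    len <- lengths[seq_len(need)]
    s <- floor(stats::runif(need, 0, chrom_len - len))
    e <- s + len
    cand_s <- c(placed_s, s); cand_e <- c(placed_e, e)
    o <- order(cand_s)
    cand_s <- cand_s[o]; cand_e <- cand_e[o]
    keep <- rep(TRUE, length(cand_s))
    last_end <- -1
    for (i in seq_along(cand_s)) {
      if (cand_s[i] > last_end) last_end <- cand_e[i] else keep[i] <- FALSE
    }
    placed_s <- cand_s[keep]; placed_e <- cand_e[keep]
    need <- n - length(placed_s)
    lengths <- sample(lengths)  # reshuffle lengths for retries
    if (need == 0L) break
  }
  if (need > 0L)
    stop("could not place ", n, " intervals on a ", chrom_len,
         " bp chromosome; reduce density or lengths")
  data.frame(start = placed_s, end = placed_e)
}

rand_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Generate a synthetic genome
#'
#' Background sequence is drawn i.i.d. at the background G+C level and then
#' CpG-depleted (CG -> CA with probability `cpg_depletion`), so that, as in
#' real vertebrate genomes, CpG o/e is low outside islands. CpG islands are
#' GC-rich, undepleted spans; repeats are a coordinate mask (the underlying
#' sequence is left unchanged).
#'
#' @param spec A [synthetic_genome_spec()].
#' @return A `map_genome`: list with `sequences` (named
#'   [Biostrings::DNAStringSet]), `cgi` (interval data frame with `id`),
#'   `repeats` (interval data frame), `seqlengths`, `variants`
#'   (genetic-artifact records, initially empty) and the generating `spec`.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  chroms <- paste0("chr", seq_len(spec$n_chromosomes))
  seqs <- character(length(chroms))
  cgi_all <- list(); rep_all <- list()
  for (ci in seq_along(chroms)) {
    len <- spec$chrom_length
    s <- rand_bases(len, spec$gc_background)
    # deplete background CpGs
    cg <- which(s[-len] == "C" & s[-1L] == "G")
    if (length(cg)) {
      kill <- cg[stats::runif(length(cg)) < spec$cpg_depletion]
      s[kill + 1L] <- "A"
    }
    # CpG islands: GC-rich, CpG-retaining
    n_cgi <- stats::rpois(1L, spec$cgi_density * len / 1e6)
    cgi <- place_intervals(n_cgi,
                           floor(stats::runif(n_cgi,
                                              spec$cgi_length_range[1L],
                                              spec$cgi_length_range[2L] + 1)),
                           len)
    for (i in seq_len(nrow(cgi)))
      s[(cgi$start[i] + 1):cgi$end[i]] <-
        rand_bases(cgi$end[i] - cgi$start[i], spec$gc_cgi)
    # repeat mask tiling ~repeat_fraction of bases, off-island
    reps <- data.frame(start = numeric(0), end = numeric(0))
    if (spec$repeat_fraction > 0) {
      rep_len <- 300L
      n_rep <- ceiling(spec$repeat_fraction * len / rep_len)
      reps <- place_with_avoid(n_rep, rep_len, len, cgi)
    }
    seqs[ci] <- paste0(s, collapse = "")
    if (nrow(cgi))
      cgi_all[[ci]] <- data.frame(chrom = chroms[ci], cgi,
                                  stringsAsFactors = FALSE)
    if (nrow(reps))
      rep_all[[ci]] <- data.frame(chrom = chroms[ci], reps,
                                  stringsAsFactors = FALSE)
  }
  cgi <- if (length(cgi_all)) do.call(rbind, cgi_all) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  reps <- if (length(rep_all)) do.call(rbind, rep_all) else
    data.frame(chrom = character(), start = numeric(), end = numeric())
  if (nrow(cgi)) cgi$id <- sprintf("cgi_%04d", seq_len(nrow(cgi)))
  sequences <- Biostrings::DNAStringSet(stats::setNames(seqs, chroms))
  structure(list(sequences = sequences,
                 cgi = cgi,
                 repeats = reps,
                 seqlengths = stats::setNames(rep(spec$chrom_length,
                                                  length(chroms)), chroms),
                 variants = list(),
                 spec = spec),
            class = "map_genome")
}

# place n intervals of fixed length avoiding `avoid` intervals
place_with_avoid <- function(n, ilen, chrom_len, avoid, max_iter = 200L) {
  placed <- data.frame(start = numeric(0), end = numeric(0))
  for (iter in seq_len(max_iter)) {
    need <- n - nrow(placed)
    if (need == 0L) break
    s <- floor(stats::runif(need, 0, chrom_len - ilen))
    cand <- data.frame(start = s, end = s + ilen)
    occupied <- rbind(avoid[c("start", "end")], placed, cand)
    # keep candidates not clashing with avoid or earlier placements
    ok <- rep(TRUE, nrow(cand))
    block <- rbind(avoid[c("start", "end")], placed)
    for (i in seq_len(nrow(cand))) {
      if (nrow(block) &&
          any(cand$start[i] < block$end & cand$end[i] > block$start)) {
        ok[i] <- FALSE
      } else {
        block <- rbind(block, cand[i, ])
      }
    }
    placed <- rbind(placed, cand[ok, , drop = FALSE])
  }
  if (nrow(placed) < n)
    stop("could not place repeat intervals; reduce repeat_fraction")
  placed <- placed[order(placed$start), , drop = FALSE]
  rownames(placed) <- NULL
  placed
}

#' @export
print.map_genome <- function(x, ...) {
  cat("<map_genome> ", length(x$sequences), " chromosome(s) x ",
      x$spec$chrom_length, " bp; ", nrow(x$cgi), " CGIs; ",
      nrow(x$repeats), " repeat intervals; ",
      length(x$variants), " genetic variant record(s)\n", sep = "")
  invisible(x)
}

# 0-based positions of the C of every CpG dinucleotide, per chromosome
cpg_positions <- function(genome) {
  lapply(stats::setNames(names(genome$sequences), names(genome$sequences)),
         function(ch) {
           Biostrings::start(Biostrings::matchPattern(
             "CG", genome$sequences[[ch]])) - 1L
         })
}

#' Assign methylation states to CpG sites
#'
#' The bulk genome is methylated; a fraction of CpG islands is constitutively
#' unmethylated (those islands are invisible to the affinity purification and
#' should never become MAP-regions). States are per-CpG weights in \[0, 1\];
#' fractional states model cell mixtures.
#'
#' @param genome A `map_genome`.
#' @param frac_cgi_methylated Fraction of CpG islands that are methylated.
#' @param background_methylation Methylation weight of non-island CpGs.
#' @param seed Seed for the island methylation assignment.
#' @return A `methylation_states`: list with `cpg` (0-based CpG positions per
#'   chromosome), `weights` (baseline weight per CpG per chromosome) and
#'   `methylated_cgi` (island ids).
#' @export
methylation_states <- function(genome, frac_cgi_methylated = 0.7,
                               background_methylation = 1,
                               seed = genome$spec$seed) {
  set.seed(seed)
  cpg <- cpg_positions(genome)
  weights <- lapply(cpg, function(p) rep(background_methylation, length(p)))
  meth_ids <- character(0)
  if (nrow(genome$cgi)) {
    meth <- stats::runif(nrow(genome$cgi)) < frac_cgi_methylated
    meth_ids <- genome$cgi$id[meth]
    for (ch in names(cpg)) {
      cg <- genome$cgi[genome$cgi$chrom == ch, , drop = FALSE]
      if (!nrow(cg)) next
      o <- order(cg$start)
      cg <- cg[o, , drop = FALSE]
      cg_meth <- meth[genome$cgi$chrom == ch][o]
      idx <- findInterval(cpg[[ch]], cg$start)  # islands are disjoint
      inside <- idx > 0 & cpg[[ch]] < cg$end[pmax(idx, 1L)]
      weights[[ch]][inside] <- as.numeric(cg_meth[idx[inside]])
    }
  }
  structure(list(cpg = cpg, weights = weights, methylated_cgi = meth_ids),
            class = "methylation_states")
}

#' Declare a group-level methylation effect
#'
#' @param variable Sample-sheet column carrying the grouping (e.g. `region`,
#'   `individual`, `sex`).
#' @param level The level of `variable` whose samples carry the effect.
#' @param cgi_ids Island ids (from the genome's `cgi` table) whose methylated
#'   signal is scaled.
#' @param effect Multiplicative fold-change (> 0) on methylated-CpG signal in
#'   the affected group; > 1 means hypermethylated there.
#' @param direction `"hyper"` or `"hypo"`; must agree with `effect`.
#' @return An `effect_spec`.
#' @export
effect_spec <- function(variable, level, cgi_ids, effect,
                        direction = if (effect > 1) "hyper" else "hypo") {
  if (effect <= 0) stop("effect must be > 0")
  direction <- match.arg(direction, c("hyper", "hypo"))
  if ((effect > 1) != (direction == "hyper") && effect != 1)
    stop("direction inconsistent with effect: hyper requires effect > 1")
  structure(list(variable = variable, level = level, cgi_ids = cgi_ids,
                 effect = effect, direction = direction),
            class = "effect_spec")
}

# stable, platform-independent small-integer seed from (seed, id)
derive_seed <- function(seed, id) {
  h <- 0
  for (k in utf8ToInt(id)) h <- (h * 31 + k) %% 2147483563
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483563) + 1L
}

# per-bin fragment rate for one sample: depth_scale * methylated-CpG weight
# per bin, scaled by any effects applying to this sample, plus per-sample
# genetic variants (CpG-loss SNPs, CpG-rich insertions)
sample_bin_rates <- function(genome, states, sample_row, effects,
                             depth_scale, bin) {
  rates <- list()
  for (ch in names(genome$sequences)) {
    len <- genome$seqlengths[[ch]]
    nbins <- ceiling(len / bin)
    w <- states$weights[[ch]]
    pos <- states$cpg[[ch]]
    # genetic variants act through the CpG-count channel only
    extra_pos <- numeric(0); extra_w <- numeric(0)
    for (v in genome$variants) {
      if (!(sample_row$individual %in% v$samples) &&
          !(sample_row$sample_id %in% v$samples)) next
      if (v$chrom != ch) next
      if (v$kind == "snp_cpg_loss") {
        w <- ifelse(pos == v$pos, 0, w)
      } else if (v$kind == "cpg_rich_insertion") {
        ins_pos <- v$pos + floor(seq(0, v$length - 1,
                                     length.out = v$n_cpg))
        extra_pos <- c(extra_pos, ins_pos)
        extra_w <- c(extra_w, rep(1, length(ins_pos)))
      }
    }
    allpos <- c(pos, extra_pos); allw <- c(w, extra_w)
    bw <- numeric(nbins)
    if (length(allpos)) {
      idx <- floor(allpos / bin) + 1L
      agg <- rowsum(allw, idx)
      bw[as.integer(rownames(agg))] <- agg[, 1L]
    }
    mult <- rep(1, nbins)
    for (ef in effects) {
      if (!identical(as.character(sample_row[[ef$variable]]),
                     as.character(ef$level))) next
      aff <- genome$cgi[genome$cgi$id %in% ef$cgi_ids &
                          genome$cgi$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(aff))) {
        b0 <- floor(aff$start[i] / bin) + 1L
        b1 <- min(nbins, floor((aff$end[i] - 1) / bin) + 1L)
        mult[b0:b1] <- mult[b0:b1] * ef$effect
      }
    }
    rates[[ch]] <- depth_scale * bw * mult
  }
  rates
}

#' Simulate MAP-seq coverage for a sample sheet
#'
#' For every sample, fragments of length `frag_length` are emitted at Poisson
#' rates proportional to the methylated-CpG weight of each `bin`-bp bin
#' (optionally scaled by group effects), and depth is the fragment pileup.
#' Expected local depth is therefore a monotonically increasing function of
#' methylated-CpG density, the defining property of the affinity-purification
#' signal; unmethylated islands yield near-zero depth.
#'
#' @param genome A `map_genome` (possibly carrying genetic artifacts, see
#'   [inject_genetic_artifacts()]).
#' @param states A `methylation_states`.
#' @param sample_sheet Data frame with `sample_id` plus every variable named
#'   by `effects`.
#' @param effects List of [effect_spec()] objects.
#' @param depth_scale Expected fragments per methylated CpG per bin.
#' @param frag_length Fragment length (bp).
#' @param bin Rate-bin width (bp).
#' @param seed Global seed; each sample's stream is derived from
#'   (`seed`, `sample_id`), so re-simulating a sample reproduces its track.
#' @return List with `tracks` (named list of `coverage_track`) and `truth`
#'   (a `truth_set` data frame of spiked intervals: chrom, start, end, id,
#'   direction, contrast; effects with fold-change 1 are excluded).
#' @export
simulate_coverage <- function(genome, states, sample_sheet, effects = list(),
                              depth_scale = 1, frag_length = 200L,
                              bin = 50L, seed = 1L) {
  for (ef in effects) {
    if (!ef$variable %in% names(sample_sheet))
      stop("effect variable '", ef$variable, "' not in sample sheet")
    unknown <- setdiff(ef$cgi_ids, genome$cgi$id)
    if (length(unknown))
      stop("effect references unknown interval id(s): ",
           paste(unknown, collapse = ", "))
  }
  if (anyNA(sample_sheet) || any(!nzchar(as.matrix(sample_sheet))))
    stop("every sample must have values for all declared variables")
  tracks <- list()
  for (si in seq_len(nrow(sample_sheet))) {
    row <- sample_sheet[si, , drop = FALSE]
    rates <- sample_bin_rates(genome, states, row, effects, depth_scale, bin)
    set.seed(derive_seed(seed, row$sample_id))
    frags <- list()
    for (ch in names(rates)) {
      lam <- rates[[ch]]
      n <- stats::rpois(length(lam), lam)
      tot <- sum(n)
      if (tot == 0L) next
      bin_start <- rep.int((seq_along(lam) - 1L) * bin, n)
      starts <- bin_start + floor(stats::runif(tot, 0, bin))
      len <- genome$seqlengths[[ch]]
      ends <- pmin(starts + frag_length, len)
      starts <- pmin(starts, len - 1)
      frags[[ch]] <- data.frame(chrom = ch, start = starts, end = ends,
                                stringsAsFactors = FALSE)
    }
    frags <- if (length(frags)) do.call(rbind, frags) else
      data.frame(chrom = character(), start = numeric(), end = numeric())
    tracks[[row$sample_id]] <- coverage_from_fragments(frags,
                                                       genome$seqlengths)
  }
  list(tracks = tracks, truth = truth_set(genome, effects))
}

#' Ground-truth spiked intervals implied by a set of effects
#'
#' @param genome A `map_genome`.
#' @param effects List of [effect_spec()]; null effects (fold-change 1) are
#'   never truths.
#' @return A `truth_set` data frame: chrom, start, end, id, direction,
#'   contrast.
#' @export
truth_set <- function(genome, effects) {
  rows <- list()
  for (ef in effects) {
    if (ef$effect == 1) next
    iv <- genome$cgi[genome$cgi$id %in% ef$cgi_ids, , drop = FALSE]
    if (nrow(iv) == 0L) next
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                 id = iv$id, direction = ef$direction,
                 contrast = paste(ef$variable, ef$level, sep = ":"),
                 stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               id = character(), direction = character(),
               contrast = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("truth_set", "data.frame")
  out
}

#' Inject genetic artifacts into a genome
#'
#' Models the two false-positive mechanisms seen when comparing genetically
#' distinct individuals: CpG-destroying SNPs (`snp_cpg_loss`) and CpG-rich
#' element insertions (`cpg_rich_insertion`, Alu-like). Artifacts change
#' coverage only through the methylated-CpG-count channel of the affected
#' samples; the insertion is represented as a locus-level gain of methylated
#' CpGs in the shared coordinate system.
#'
#' @param genome A `map_genome`.
#' @param kind `"snp_cpg_loss"` or `"cpg_rich_insertion"`.
#' @param positions Data frame with `chrom` and `pos` (0-based). For SNPs,
#'   `pos` must be the C of an existing CpG.
#' @param samples Character vector of affected sample ids or individual
#'   labels.
#' @param insert_length,insert_cpgs Span and methylated-CpG content of each
#'   insertion.
#' @return The genome with the artifact recorded in `$variants` (an empty
#'   `positions` returns the genome unchanged).
#' @export
inject_genetic_artifacts <- function(genome, kind, positions, samples,
                                     insert_length = 300L,
                                     insert_cpgs = 25L) {
  kind <- match.arg(kind, c("snp_cpg_loss", "cpg_rich_insertion"))
  if (nrow(positions) == 0L) return(genome)
  cpg <- cpg_positions(genome)
  for (i in seq_len(nrow(positions))) {
    ch <- positions$chrom[i]; pos <- positions$pos[i]
    if (!ch %in% names(genome$sequences))
      stop("position on unknown chromosome ", ch)
    if (pos < 0 || pos >= genome$seqlengths[[ch]])
      stop("position outside the genome")
    if (kind == "snp_cpg_loss") {
      if (!pos %in% cpg[[ch]])
        stop("snp_cpg_loss position ", pos, " on ", ch, " is not a CpG site")
      genome$variants[[length(genome$variants) + 1L]] <-
        list(kind = kind, chrom = ch, pos = pos, samples = samples)
    } else {
      if (pos + insert_length > genome$seqlengths[[ch]])
        stop("insertion overlapping a chromosome end")
      genome$variants[[length(genome$variants) + 1L]] <-
        list(kind = kind, chrom = ch, pos = pos, samples = samples,
             length = insert_length, n_cpg = insert_cpgs)
    }
  }
  genome
}

#' Methylated-CpG count seen by one sample over an interval
#'
#' Accounts for the sample's genetic variants; this is the quantity the
#' coverage rate of a bin is proportional to.
#'
#' @param genome A `map_genome`.
#' @param states A `methylation_states`.
#' @param sample_row One row of the sample sheet (needs `sample_id` and
#'   `individual` when variants are keyed by individual).
#' @param chrom,start,end Interval (0-based half-open).
#' @return Total methylated-CpG weight in the interval.
#' @export
methylated_cpg_count <- function(genome, states, sample_row,
                                 chrom, start, end) {
  pos <- states$cpg[[chrom]]
  w <- states$weights[[chrom]]
  extra <- 0
  for (v in genome$variants) {
    if (!(sample_row$individual %in% v$samples) &&
        !(sample_row$sample_id %in% v$samples)) next
    if (v$chrom != chrom) next
    if (v$kind == "snp_cpg_loss") {
      w <- ifelse(pos == v$pos, 0, w)
    } else {
      ins <- v$pos + floor(seq(0, v$length - 1, length.out = v$n_cpg))
      extra <- extra + sum(ins >= start & ins < end)
    }
  }
  sum(w[pos >= start & pos < end]) + extra
}

#' Expected coverage depth under the generative model
#'
#' Computes the exact expected per-base pileup for one sample (no Monte
#' Carlo): fragment starts are uniform within each rate bin, so the expected
#' depth at a base is the trailing `frag_length`-window sum of the per-base
#' start rate.
#'
#' @inheritParams simulate_coverage
#' @param sample_row One sample-sheet row.
#' @param windows Optional interval data frame; if given, returns per-window
#'   mean expected depth instead of per-base vectors.
#' @return Named list of per-base expected-depth vectors, or a numeric vector
#'   of per-window means.
#' @export
expected_depth <- function(genome, states, sample_row, effects = list(),
                           depth_scale = 1, frag_length = 200L, bin = 50L,
                           windows = NULL) {
  rates <- sample_bin_rates(genome, states, sample_row, effects,
                            depth_scale, bin)
  perbase <- lapply(names(rates), function(ch) {
    len <- genome$seqlengths[[ch]]
    r <- rep(rates[[ch]] / bin, each = bin)[seq_len(len)]
    cs <- cumsum(r)
    lag <- c(rep(0, frag_length), cs[seq_len(len - frag_length)])
    cs - lag
  })
  names(perbase) <- names(rates)
  if (is.null(windows)) return(perbase)
  vapply(seq_len(nrow(windows)), function(i) {
    v <- perbase[[windows$chrom[i]]]
    mean(v[(windows$start[i] + 1):windows$end[i]])
  }, numeric(1))
}
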