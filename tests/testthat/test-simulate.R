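small_spec <- function(...) {
  synthetic_genome_spec(chrom_length = 1e5, cgi_density = 40,
                        repeat_fraction = 0.03, seed = 5, ...)
}

test_that("genome generation is deterministic and honours its spec", {
  g1 <- make_genome(small_spec())
  g2 <- make_genome(small_spec())
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$cgi, g2$cgi)
  expect_identical(g1$repeats, g2$repeats)

  # repeat_fraction = 0 gives an empty repeat mask
  g0 <- make_genome(synthetic_genome_spec(chrom_length = 5e4,
                                          repeat_fraction = 0, seed = 2))
  expect_equal(nrow(g0$repeats), 0L)

  # invalid configurations error
  expect_error(synthetic_genome_spec(chrom_length = 1000,
                                     cgi_length_range = c(500, 2000)),
               "exceeds chrom_length")
  expect_error(synthetic_genome_spec(gc_cgi = 0.3, gc_background = 0.41),
               "GC-rich")
  expect_error(synthetic_genome_spec(repeat_fraction = 1), "repeat_fraction")
})

test_that("CGI count is Poisson around density x Mb", {
  counts <- vapply(1:100, function(s) {
    g <- make_genome(synthetic_genome_spec(chrom_length = 1e6,
                                           cgi_density = 10,
                                           repeat_fraction = 0, seed = s))
    nrow(g$cgi)
  }, numeric(1))
  # mean within 3 standard errors of 10 (SE = sqrt(10/100))
  expect_lt(abs(mean(counts) - 10), 3 * sqrt(10 / 100))
})

test_that("CGIs are GC- and CpG-enriched over the depleted background", {
  g <- make_genome(small_spec())
  st_cgi <- interval_seq_stats(g$cgi, g$sequences)
  # background sampled away from islands
  bg <- intervals("chr1", seq(0, 9e4, by = 1e4), seq(0, 9e4, by = 1e4) + 500)
  bg <- bg[!overlaps_any(bg, g$cgi), , drop = FALSE]
  st_bg <- interval_seq_stats(bg, g$sequences)
  expect_gt(mean(st_cgi$gc_fraction), mean(st_bg$gc_fraction))
  expect_gt(mean(st_cgi$cpg_oe), 2 * mean(st_bg$cpg_oe))
  # repeats tile roughly the requested fraction
  expect_equal(sum(g$repeats$end - g$repeats$start) / 1e5, 0.03,
               tolerance = 0.01)
})

test_that("coverage is deterministic, methylation-driven and effect-scaled", {
  g <- make_genome(small_spec())
  st <- methylation_states(g)
  sheet <- group_sheet(2, 2)
  sim1 <- simulate_coverage(g, st, sheet, seed = 9)
  sim2 <- simulate_coverage(g, st, sheet, seed = 9)
  expect_identical(lapply(sim1$tracks, `[[`, "rle"),
                   lapply(sim2$tracks, `[[`, "rle"))

  # zero methylation everywhere: all-zero depth
  st0 <- st
  st0$weights <- lapply(st0$weights, function(w) w * 0)
  sim0 <- simulate_coverage(g, st0, sheet, seed = 9)
  expect_true(all(vapply(sim0$tracks, function(tr)
    sum(S4Vectors::runValue(tr$rle$chr1)) == 0, logical(1))))

  # unmethylated islands stay near zero depth while methylated ones are
  # strongly enriched
  meth <- g$cgi[g$cgi$id %in% st$methylated_cgi, , drop = FALSE]
  unmeth <- g$cgi[!g$cgi$id %in% st$methylated_cgi, , drop = FALSE]
  d_meth <- mean(mean_depth(sim1$tracks[[1L]], meth))
  d_unmeth <- mean(mean_depth(sim1$tracks[[1L]], unmeth))
  expect_gt(d_meth, 10 * max(d_unmeth, 0.1))
})

test_that("expected depth is monotone in methylated-CpG count", {
  # controlled grid: isolated 50-bp loci carrying 0, 1, ..., 12 CpGs, spaced
  # far beyond the fragment length so no signal spills between them
  counts <- 0:12
  s <- rep("A", 3e4)
  for (k in counts) {
    if (k == 0) next
    at <- 2000 * (k + 1) + seq(0, by = 4, length.out = k)
    for (p in at) { s[p + 1] <- "C"; s[p + 2] <- "G" }
  }
  g <- structure(list(
    sequences = Biostrings::DNAStringSet(c(chr1 = paste0(s, collapse = ""))),
    cgi = data.frame(chrom = character(0), start = numeric(0),
                     end = numeric(0), id = character(0)),
    repeats = data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0)),
    seqlengths = c(chr1 = 30000L), variants = list(),
    spec = list(seed = 1L)), class = "map_genome")
  st <- methylation_states(g, seed = 1)
  windows <- intervals("chr1", 2000 * (counts + 1), 2000 * (counts + 1) + 50)
  ed <- expected_depth(g, st, group_sheet(1, 1)[1L, ], windows = windows)
  expect_true(all(diff(ed) > 0))
  expect_equal(ed[1], 0)
})

test_that("a two-fold effect doubles expected and empirical depth at truth intervals", {
  g <- make_genome(small_spec())
  st <- methylation_states(g)
  ids <- methylated_cgi_ids(g, st)
  ef <- list(effect_spec("group", "B", ids[1:2], 2.0))
  sheet <- group_sheet(1, 1)
  tgt <- g$cgi[g$cgi$id %in% ids[1:2], ]
  # interior of the island (one fragment length in from the start) receives
  # fragments only from scaled bins, so the expected ratio is exactly 2
  interior <- transform(tgt, start = start + 200)
  e_a <- expected_depth(g, st, sheet[1L, ], ef, windows = interior)
  e_b <- expected_depth(g, st, sheet[2L, ], ef, windows = interior)
  expect_equal(e_b / e_a, rep(2, nrow(tgt)), tolerance = 1e-9)

  # empirical mean depth ratio over 50 replicate samples approximates 2
  big <- group_sheet(50, 50)
  sim <- simulate_coverage(g, st, big, ef, seed = 33)
  d_a <- rowMeans(vapply(big$sample_id[big$group == "A"], function(s)
    mean_depth(sim$tracks[[s]], tgt), numeric(nrow(tgt))))
  d_b <- rowMeans(vapply(big$sample_id[big$group == "B"], function(s)
    mean_depth(sim$tracks[[s]], tgt), numeric(nrow(tgt))))
  expect_equal(mean(d_b / d_a), 2, tolerance = 0.1)
})

test_that("truth sets contain exactly the non-null effects", {
  g <- make_genome(small_spec())
  st <- methylation_states(g)
  ids <- methylated_cgi_ids(g, st)
  ef <- list(effect_spec("group", "B", ids[1], 2.0),
             effect_spec("group", "B", ids[2], 1.0, direction = "hyper"))
  ts <- truth_set(g, ef)
  expect_equal(ts$id, ids[1])
  expect_true(all(overlaps_any(ts, g$cgi)))
  # unknown interval id errors at simulation time
  bad <- list(effect_spec("group", "B", "cgi_9999", 2.0))
  expect_error(simulate_coverage(g, st, group_sheet(1, 1), bad, seed = 1),
               "unknown interval")
})

test_that("genetic artifacts act through the CpG-count channel", {
  g <- make_genome(small_spec())
  st <- methylation_states(g)
  sheet <- group_sheet(1, 1)
  cpg1 <- st$cpg$chr1[100]

  # SNP CpG loss: the affected sample's methylated-CpG count drops by one
  g_snp <- inject_genetic_artifacts(g, "snp_cpg_loss",
                                    data.frame(chrom = "chr1", pos = cpg1),
                                    samples = "s01")
  before <- methylated_cpg_count(g, st, sheet[1L, ], "chr1",
                                 cpg1 - 100, cpg1 + 100)
  after <- methylated_cpg_count(g_snp, st, sheet[1L, ], "chr1",
                                cpg1 - 100, cpg1 + 100)
  expect_equal(before - after, 1)
  other <- methylated_cpg_count(g_snp, st, sheet[2L, ], "chr1",
                                cpg1 - 100, cpg1 + 100)
  expect_equal(other, before)

  # CpG-rich insertion raises expected depth only in the carrier
  pos <- 50000
  g_ins <- inject_genetic_artifacts(g, "cpg_rich_insertion",
                                    data.frame(chrom = "chr1", pos = pos),
                                    samples = "i01")
  locus <- intervals("chr1", pos, pos + 300)
  e_car <- expected_depth(g_ins, st, sheet[1L, ], windows = locus)
  e_non <- expected_depth(g_ins, st, sheet[2L, ], windows = locus)
  expect_gt(e_car, e_non)

  # empty positions: genome unchanged
  expect_identical(inject_genetic_artifacts(
    g, "snp_cpg_loss", data.frame(chrom = character(0), pos = numeric(0)),
    samples = "s01"), g)

  # guard rails
  expect_error(inject_genetic_artifacts(
    g, "cpg_rich_insertion", data.frame(chrom = "chr1", pos = 99990),
    samples = "s01"), "chromosome end")
  expect_error(inject_genetic_artifacts(
    g, "snp_cpg_loss", data.frame(chrom = "chr1", pos = cpg1 + 1),
    samples = "s01"), "not a CpG")
})
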