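test_that("sequence statistics match hand computation", {
  st <- seq_stats(c("ATGC", "CGCGCG", "AAAA"))
  expect_equal(st$gc_fraction, c(0.5, 1, 0))
  expect_equal(st$cpg_per_100bp, c(0, 100 * 3 / 6, 0))
  # CGCGCG: 3 CGs, 3 Cs, 3 Gs, len 6 -> o/e = 3*6/(3*3) = 2
  expect_equal(st$cpg_oe[2], 2)
  # no C or no G: o/e undefined
  expect_true(is.na(st$cpg_oe[3]))
  expect_true(is.na(seq_stats("CCCC")$cpg_oe))
  # N bases excluded from denominators
  expect_equal(seq_stats("ATGCNNNN")$gc_fraction, 0.5)
})

test_that("reverse complement preserves gc and CpG count", {
  set.seed(17)
  for (rep_i in 1:20) {
    s <- paste0(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    a <- seq_stats(s); b <- seq_stats(rc)
    expect_equal(a$gc_fraction, b$gc_fraction)
    expect_equal(a$cpg_per_100bp, b$cpg_per_100bp)  # CG is its own revcomp
  }
})

test_that("annotation hierarchy assigns exactly one category by precedence", {
  ann <- toy_annotation()
  # geneA (+): TSS at 10000; geneB (-): TSS at 45999
  dmr <- intervals("chr1",
                   c(10300,   # TSS window (+300) and exon overlap -> TSS
                     15100,   # exon 2 of geneA, outside TSS window
                     12000,   # intron of geneA
                     9000,    # 501-2000 bp 5' of geneA TSS -> upstream
                     46800,   # 5' of geneB (minus strand) -> upstream
                     30000,   # between genes, >2 kb from any TSS
                     5000),   # far upstream -> intergenic
                   c(10350, 15150, 12050, 9050, 46850, 30050, 5050))
  got <- as.character(classify_annotation(dmr, ann))
  expect_equal(got, c("TSS", "exonic", "intronic", "upstream", "upstream",
                      "intergenic", "intergenic"))
  # totality: random intervals all receive exactly one category
  set.seed(29)
  rnd <- intervals("chr1", s <- sample(0:49000, 50), s + 200)
  cats <- classify_annotation(rnd, ann)
  expect_false(anyNA(cats))
  # an interval spanning the gene end takes the best category it touches
  two <- intervals("chr1", 15400, 16300)
  expect_equal(as.character(classify_annotation(two, ann)), "exonic")
  # gene without exons is rejected at construction
  expect_error(gene_annotation(
    data.frame(chrom = "chr1", start = 0, end = 100, strand = "+",
               id = "g1"),
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               gene_id = character(0))), "no exons")
})

test_that("CGI co-localization records signed offsets within the flank", {
  cgis <- intervals("chr1", c(10000, 40000), c(11000, 41000))
  # DMR centred exactly on the first island centre
  d0 <- intervals("chr1", 10400, 10600)
  res <- cgi_colocalization(d0, cgis)
  expect_equal(res$offsets$offset, 0)
  # 6 kb away with a 5 kb flank: excluded
  far <- intervals("chr1", 16400, 16600)
  expect_equal(nrow(cgi_colocalization(far, cgis)$offsets), 0L)
  # signed: DMR to the left of the centre gets a negative offset
  left <- intervals("chr1", 9000, 9200)
  expect_lt(cgi_colocalization(left, cgis)$offsets$offset, 0)
})

test_that("uniform random DMRs give a flat offset distribution", {
  set.seed(37)
  cgis <- intervals("chr1", 50000, 51000)
  p <- replicate(20, {
    s <- runif(300, 40000, 60000)
    dmrs <- intervals("chr1", s, s + 100)
    off <- cgi_colocalization(dmrs, cgis, flank = 5000)$offsets$offset
    suppressWarnings(ks.test(off, "punif", -5000, 5000)$p.value)
  })
  # non-significant in the clear majority of seeds
  expect_gt(mean(p > 0.01), 0.8)
})

test_that("arm percentile distribution partitions arms and normalizes by MAP-regions", {
  set.seed(51)
  s <- sort(sample(0:99000, 400))
  maps <- intervals("chr1", s, s + 500)
  arms <- data.frame(chrom = "chr1", start = 0, end = 1e5,
                     centromeric_end = "start", stringsAsFactors = FALSE)
  # dmrs == map_regions: ratio 1 in every occupied bin
  res <- arm_percentile_distribution(maps, maps, arms)
  expect_equal(nrow(res), 100L)
  expect_true(all(res$ratio[res$n_map > 0] == 1))
  expect_equal(sum(res$n_map), nrow(maps))  # bins partition the arm

  # all DMRs in the terminal 10%: zero ratio wherever MAP-regions exist below
  tel <- maps[interval_midpoints(maps) >= 90000, , drop = FALSE]
  res <- arm_percentile_distribution(tel, maps, arms)
  expect_true(all(res$ratio[res$percentile <= 90 & res$n_map > 0] == 0))
  expect_true(all(res$n_dmr[res$percentile > 90] >= 0))

  # empty MAP bins are NA, not infinite
  gap_maps <- maps[interval_midpoints(maps) < 50000, , drop = FALSE]
  res <- arm_percentile_distribution(maps, gap_maps, arms)
  expect_true(all(is.na(res$ratio[res$n_map == 0])))

  # random placement: mean bin ratio approximates the global ratio
  dm <- maps[sample(nrow(maps), 100), ]
  res <- arm_percentile_distribution(dm, maps, arms)
  expect_equal(mean(res$ratio, na.rm = TRUE), 100 / 400, tolerance = 0.1)

  # orientation: percentile 100 is telomere-proximal
  res <- arm_percentile_distribution(tel, maps, arms)
  expect_gt(sum(res$n_dmr[res$percentile > 90]), 0)
  arms_flip <- transform(arms, centromeric_end = "end")
  res_f <- arm_percentile_distribution(tel, maps, arms_flip)
  expect_gt(sum(res_f$n_dmr[res_f$percentile <= 10]), 0)
  expect_equal(sum(res_f$n_dmr[res_f$percentile > 90]), 0)
})
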