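# helper: a normalized window_matrix whose values are set directly, for
# exercising the modelling stage in isolation
matrix_with_values <- function(values, chrom = "chr1") {
  w <- tile_windows(intervals(chrom, 0, 50 * nrow(values), id = "r1"))
  wm <- structure(list(windows = w, samples = colnames(values),
                       depth = values, values = values, normalized = TRUE,
                       offset = 0.1, scale = "ratio"),
                  class = "window_matrix")
  wm
}

two_group_design <- function(values, n_a, n_b) {
  design_spec(group_sheet(n_a, n_b), "group", c("A", "B"))
}

test_that("window models match the closed-form two-group fit", {
  # identical groups: zero fold change and zero residual variance (the
  # degenerate all-zero-variance case warns and falls back)
  v <- matrix(2, 4, 4, dimnames = list(NULL, sprintf("s%02d", 1:4)))
  fit <- suppressWarnings(dmr_fit(matrix_with_values(v),
                                  two_group_design(v, 2, 2)))
  expect_equal(unname(fit$results$log2_fc), rep(0, 4))
  expect_equal(unname(fit$s2), rep(0, 4))

  # group A {1,1}, group B {2,2} on log2 scale: coefficient difference -1
  # for A vs B (B is 1 log2 unit higher)
  v <- matrix(2^c(1, 1, 2, 2), 2, 4, byrow = TRUE,
              dimnames = list(NULL, sprintf("s%02d", 1:4)))
  fit <- suppressWarnings(dmr_fit(matrix_with_values(v),
                                  two_group_design(v, 2, 2)))
  expect_equal(unname(fit$results$log2_fc), rep(-1, 2))
  expect_equal(fit$results$direction, rep("hypo", 2))

  # random matrix vs lm() ordinary least squares, with moderation disabled
  set.seed(31)
  v <- matrix(2^rnorm(60), 10, 6, dimnames = list(NULL, sprintf("s%02d", 1:6)))
  sheet <- group_sheet(3, 3)
  fit <- dmr_fit(matrix_with_values(v), design_spec(sheet, "group",
                                                    c("A", "B")), d0 = 0)
  g <- factor(sheet$group, levels = c("B", "A"))
  for (i in 1:10) {
    lmfit <- lm(log2(v[i, ]) ~ g)
    expect_equal(unname(fit$results$log2_fc[i]),
                 unname(coef(lmfit)["gA"]), tolerance = 1e-10)
    expect_equal(unname(fit$s2[i]), summary(lmfit)$sigma^2,
                 tolerance = 1e-10)
    expect_equal(unname(fit$results$p_value[i]),
                 summary(lmfit)$coefficients["gA", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
})

test_that("a contrast level with fewer than two samples errors", {
  v <- matrix(1, 3, 3, dimnames = list(NULL, sprintf("s%02d", 1:3)))
  expect_error(dmr_fit(matrix_with_values(v),
                       design_spec(group_sheet(1, 2), "group", c("A", "B"))),
               ">= 2 samples")
})

test_that("moderation limits: d0 = 0 gives the ordinary t, d0 = Inf pools", {
  set.seed(8)
  s2 <- rgamma(100, 2)
  m0 <- moderate_variances(s2, df = 10, d0 = 0)
  expect_equal(m0$post, s2)
  mInf <- moderate_variances(s2, df = 10, d0 = Inf)
  expect_equal(unname(mInf$post), rep(mInf$s02, 100))
  # posterior variance interpolates between observation and prior
  m <- moderate_variances(s2, df = 10)
  expect_true(all(m$post >= pmin(s2, m$s02) - 1e-12))
  expect_true(all(m$post <= pmax(s2, m$s02) + 1e-12))
})

test_that("moderation recovers the prior from simulated variances", {
  set.seed(12)
  d0_hat <- replicate(20, {
    s2 <- simulate_prior_variances(5000, d0 = 4, s02 = 1, df = 18)
    moderate_variances(s2, df = 18)$d0
  })
  expect_lt(abs(mean(d0_hat) - 4) / 4, 0.25)
})

test_that("moderation agrees with an independent empirical-Bayes fit", {
  # cross-check the prior estimate and moderated t against limma on a small
  # two-group data set
  set.seed(77)
  sigma <- sqrt(4 / rchisq(200, df = 4))  # heterogeneous true variances
  y <- matrix(rnorm(200 * 8), 200, 8) * sigma
  y[1:10, 5:8] <- y[1:10, 5:8] + 2
  design <- cbind(1, rep(0:1, each = 4))
  lf <- limma::eBayes(limma::lmFit(y, design))
  v <- matrix(2^y, 200, 8, dimnames = list(NULL, sprintf("s%02d", 1:8)))
  fit <- dmr_fit(matrix_with_values(v),
                 design_spec(group_sheet(4, 4), "group", c("B", "A")))
  expect_equal(fit$d0, lf$df.prior, tolerance = 1e-3)
  expect_equal(fit$s02, lf$s2.prior, tolerance = 1e-3)
  expect_equal(unname(fit$results$t), unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(unname(fit$results$p_value), unname(lf$p.value[, 2]),
               tolerance = 1e-6)
})

test_that("all-zero variances fall back to the ordinary t with a warning", {
  expect_warning(m <- moderate_variances(rep(0, 5), df = 4),
                 "falling back")
  expect_true(all(m$post > 0))
})

test_that("bh_adjust matches the hand-computed step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("bh_adjust equals brute-force step-up enumeration", {
  set.seed(19)
  for (rep_i in 1:200) {
    p <- runif(sample(1:1000, 1L))^sample(1:3, 1L)
    expect_equal(bh_adjust(p), bf_bh(p), tolerance = 1e-12)
  }
})

sig_windows <- function(starts, adj_p, direction = "hyper", chrom = "chr1",
                        width = 50) {
  data.frame(chrom = chrom, start = starts, end = starts + width,
             adj_p = adj_p, direction = direction, stringsAsFactors = FALSE)
}

test_that("knitting follows the three-windows-within-span rule", {
  # three significant hyper windows at 0, 200, 400: one DMR [0, 450)
  w <- sig_windows(c(0, 200, 400), 0.001)
  d <- knit_dmrs(w)
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 0)
  expect_equal(d$end, 450)
  expect_equal(d$n_sig_windows, 3L)

  # two significant windows never make a DMR
  expect_equal(nrow(knit_dmrs(sig_windows(c(0, 200), 0.001))), 0L)

  # a gap of 800 bp breaks the chain before it reaches three windows
  expect_equal(nrow(knit_dmrs(sig_windows(c(0, 200, 1000), 0.001))), 0L)

  # opposite directions never co-knit
  w <- rbind(sig_windows(c(0, 200), 0.001, "hyper"),
             sig_windows(400, 0.001, "hypo"))
  expect_equal(nrow(knit_dmrs(w)), 0L)

  # non-significant windows are invisible to the chain
  w <- sig_windows(c(0, 200, 400), c(0.001, 0.5, 0.001))
  expect_equal(nrow(knit_dmrs(w)), 0L)

  # no significant windows: empty set, no error
  expect_equal(nrow(knit_dmrs(sig_windows(c(0, 200, 400), 0.9))), 0L)
})

test_that("knitting equals the exhaustive-subset oracle", {
  set.seed(23)
  for (rep_i in 1:60) {
    n <- sample(3:20, 1L)
    starts <- sort(sample(seq(0, 4000, by = 50), n))
    w <- sig_windows(starts, runif(n)^2,
                     direction = sample(c("hyper", "hypo"), n, TRUE))
    for (anchor in c("start", "end")) {
      got <- as.data.frame(knit_dmrs(w, alpha = 0.05, anchor = anchor))
      want <- bf_knit(w, alpha = 0.05, span = 500, min_windows = 3,
                      anchor = anchor)
      expect_equal(got[c("chrom", "start", "end", "direction",
                         "n_sig_windows", "min_adj_p")], want)
    }
  }
})

test_that("swapping contrast levels flips every direction and nothing else", {
  set.seed(41)
  v <- matrix(2^rnorm(400), 50, 8, dimnames = list(NULL, sprintf("s%02d", 1:8)))
  v[1:10, 5:8] <- v[1:10, 5:8] * 4
  sheet <- group_sheet(4, 4)
  wm <- matrix_with_values(v)
  f1 <- dmr_fit(wm, design_spec(sheet, "group", c("A", "B")))
  f2 <- dmr_fit(wm, design_spec(sheet, "group", c("B", "A")))
  expect_equal(f1$results$log2_fc, -f2$results$log2_fc)
  expect_equal(f1$results$p_value, f2$results$p_value)
  expect_equal(f1$results$adj_p, f2$results$adj_p)
  expect_true(all(f1$results$direction != f2$results$direction))
  d1 <- knit_dmrs(f1, alpha = 0.05)
  d2 <- knit_dmrs(f2, alpha = 0.05)
  expect_equal(d1$start, d2$start)
  expect_true(all(d1$direction != d2$direction))
})

test_that("permuting sample columns with a matching design leaves calls unchanged", {
  set.seed(43)
  v <- matrix(2^rnorm(240), 30, 8, dimnames = list(NULL, sprintf("s%02d", 1:8)))
  v[1:8, 1:4] <- v[1:8, 1:4] * 3
  sheet <- group_sheet(4, 4)
  wm1 <- matrix_with_values(v)
  perm <- sample(8)
  wm2 <- matrix_with_values(v[, perm])
  design <- design_spec(sheet, "group", c("A", "B"))
  d1 <- as.data.frame(call_dmrs(wm1, design, alpha = 0.05))
  d2 <- as.data.frame(call_dmrs(wm2, design, alpha = 0.05))
  attr(d1, "fit") <- NULL; attr(d2, "fit") <- NULL
  expect_equal(d1, d2)
})
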