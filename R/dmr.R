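#' Specify the design of a window-level contrast
#'
#' One categorical biological variable is modelled at a time; the contrast is
#' either two named levels or one level against the rest of the samples.
#'
#' @param sample_sheet Data frame with `sample_id` and the variable column.
#' @param variable Name of the sample-sheet column to model.
#' @param contrast Character pair `c(A, B)`: A is the group of interest, B a
#'   second level or `"rest"` for level-versus-rest. Hypermethylation means
#'   higher signal in A.
#' @return A `design_spec`: list with `variable`, `groups` (named
#'   sample-to-level map) and `contrast`.
#' @export
design_spec <- function(sample_sheet, variable, contrast) {
  if (!variable %in% names(sample_sheet))
    stop("variable '", variable, "' not in sample sheet")
  if (length(contrast) != 2L) stop("contrast must be a pair of levels")
  groups <- stats::setNames(as.character(sample_sheet[[variable]]),
                            sample_sheet$sample_id)
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("every sample must be assigned exactly one level")
  lv <- unique(groups)
  if (!contrast[1L] %in% lv)
    stop("contrast level '", contrast[1L], "' absent from '", variable, "'")
  if (contrast[2L] != "rest" && !contrast[2L] %in% lv)
    stop("contrast level '", contrast[2L], "' absent from '", variable, "'")
  structure(list(variable = variable, groups = groups, contrast = contrast),
            class = "design_spec")
}

contrast_samples <- function(design, samples) {
  g <- design$groups[samples]
  if (anyNA(g)) stop("matrix contains samples absent from the design")
  a <- samples[g == design$contrast[1L]]
  b <- if (design$contrast[2L] == "rest") {
    samples[g != design$contrast[1L]]
  } else {
    samples[g == design$contrast[2L]]
  }
  if (length(a) < 2L || length(b) < 2L)
    stop("each contrast level needs >= 2 samples (residual variance is ",
         "undefined otherwise)")
  list(a = a, b = b)
}

#' Fit moderated window-level models
#'
#' For every 50-bp window, the normalized log2 ratio-to-reference values are
#' fitted with a two-group means model; per-window residual variances are
#' shrunk toward an empirical-Bayes prior ([moderate_variances()]) and a
#' moderated t-statistic with `df + d0` degrees of freedom tests the group
#' difference. P-values are Benjamini-Hochberg adjusted across windows.
#'
#' @param wm A normalized `window_matrix`.
#' @param design A [design_spec()].
#' @param d0 Optionally force the moderation prior df (mainly for testing
#'   limit behaviour).
#' @return A `dmr_fit` object: the window table augmented with `log2_fc`
#'   (group A minus group B on log2 scale), `t`, `p_value`, `adj_p`,
#'   `direction`, plus the fitted group means, residual variances and the
#'   estimated prior (`d0`, `s02`).
#' @export
dmr_fit <- function(wm, design, d0 = NULL) {
  stopifnot(inherits(wm, "window_matrix"))
  if (!wm$normalized)
    stop("window matrix must be normalized before model fitting")
  y <- if (identical(wm$scale, "log2")) wm$values else log2(wm$values)
  grp <- contrast_samples(design, wm$samples)
  ya <- y[, grp$a, drop = FALSE]
  yb <- y[, grp$b, drop = FALSE]
  na <- length(grp$a); nb <- length(grp$b)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  rss <- rowSums((ya - ma)^2) + rowSums((yb - mb)^2)
  df <- na + nb - 2L
  s2 <- rss / df
  mod <- moderate_variances(s2, df, d0 = d0)
  se <- sqrt(mod$post * (1 / na + 1 / nb))
  lfc <- ma - mb
  tstat <- lfc / se
  df_total <- df + mod$d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  res <- wm$windows
  res$log2_fc <- lfc
  res$t <- tstat
  res$p_value <- p
  res$adj_p <- bh_adjust(p)
  res$direction <- ifelse(lfc < 0, "hypo", "hyper")
  structure(list(results = res, mean_a = ma, mean_b = mb, s2 = s2,
                 df = df, d0 = mod$d0, s02 = mod$s02,
                 posterior_s2 = mod$post,
                 design = design, samples = wm$samples,
                 groups = grp, y = y),
            class = "dmr_fit")
}

#' @export
print.dmr_fit <- function(x, ...) {
  cat("<dmr_fit> ", nrow(x$results), " windows; contrast ",
      x$design$variable, ": ", x$design$contrast[1L], " vs ",
      x$design$contrast[2L], " (", length(x$groups$a), " vs ",
      length(x$groups$b), " samples)\n", sep = "")
  cat("  moderation prior: d0 = ", format(x$d0, digits = 4),
      ", s0^2 = ", format(x$s02, digits = 4), "\n", sep = "")
  cat("  windows with BH-adjusted P < 0.01: ",
      sum(x$results$adj_p < 0.01), "\n", sep = "")
  invisible(x)
}

#' @export
summary.dmr_fit <- function(object, alpha = 0.01, ...) {
  r <- object$results
  sig <- r$adj_p < alpha
  out <- list(n_windows = nrow(r),
              n_significant = sum(sig),
              n_hyper = sum(sig & r$direction == "hyper"),
              n_hypo = sum(sig & r$direction == "hypo"),
              d0 = object$d0, s02 = object$s02, alpha = alpha,
              contrast = object$design$contrast,
              variable = object$design$variable)
  class(out) <- "summary.dmr_fit"
  out
}

#' @export
print.summary.dmr_fit <- function(x, ...) {
  cat("Window-level moderated contrast (", x$variable, ": ",
      x$contrast[1L], " vs ", x$contrast[2L], ")\n", sep = "")
  cat("  windows tested:        ", x$n_windows, "\n")
  cat("  significant (adj P < ", x$alpha, "): ", x$n_significant,
      " (", x$n_hyper, " hyper, ", x$n_hypo, " hypo)\n", sep = "")
  cat("  moderation prior:      d0 = ", format(x$d0, digits = 4),
      ", s0^2 = ", format(x$s02, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.dmr_fit <- function(object, ...) {
  stats::setNames(object$results$log2_fc, object$results$window_id)
}

#' @export
residuals.dmr_fit <- function(object, ...) {
  fitted <- object$y
  fitted[, object$groups$a] <- object$mean_a
  fitted[, object$groups$b] <- object$mean_b
  object$y - fitted
}

#' @export
plot.dmr_fit <- function(x, alpha = 0.01, ...) {
  r <- x$results
  sig <- r$adj_p < alpha
  plot(r$log2_fc, -log10(pmax(r$p_value, 1e-300)),
       pch = 20, col = ifelse(sig, ifelse(r$log2_fc > 0, "firebrick",
                                          "steelblue"), "grey70"),
       xlab = "log2 fold change (A vs B)", ylab = "-log10 P",
       main = paste(x$design$variable, ":", x$design$contrast[1L], "vs",
                    x$design$contrast[2L]), ...)
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: `adj_i = min over j >= rank(i) of m*p_(j)/j`,
#' capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, order-preserving.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Knit significant windows into DMRs
#'
#' Windows with BH-adjusted P below `alpha` are chained per chromosome,
#' direction and contrast while each successive significant window starts
#' within `span` bp of the previous one (`anchor = "start"`; the
#' end-to-start variant is available with `anchor = "end"`). Chains with at
#' least `min_windows` windows become DMRs spanning the first to the last
#' window; hyper- and hypomethylated windows never co-knit.
#'
#' @param results A `dmr_fit` or its window-results data frame (needs chrom,
#'   start, end, adj_p, direction).
#' @param alpha Significance threshold on adjusted P (default 0.01).
#' @param span Maximum spacing (bp) between consecutive significant windows.
#' @param min_windows Minimum significant windows per DMR (default 3).
#' @param contrast Contrast label stored on the records (taken from the fit
#'   when available).
#' @param anchor Spacing anchor, `"start"` (default) or `"end"`.
#' @return A `dmr_set` data frame: chrom, start, end, direction,
#'   n_sig_windows, min_adj_p, contrast.
#' @export
knit_dmrs <- function(results, alpha = 0.01, span = 500L, min_windows = 3L,
                      contrast = NULL, anchor = c("start", "end")) {
  anchor <- match.arg(anchor)
  if (inherits(results, "dmr_fit")) {
    if (is.null(contrast))
      contrast <- paste0(results$design$variable, ":",
                         results$design$contrast[1L])
    results <- results$results
  }
  if (is.null(contrast)) contrast <- "contrast"
  sig <- results[results$adj_p < alpha, , drop = FALSE]
  recs <- list()
  if (nrow(sig)) {
    for (key in unique(paste(sig$chrom, sig$direction))) {
      s <- sig[paste(sig$chrom, sig$direction) == key, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      if (nrow(s) > 1L) {
        gap <- if (anchor == "start") diff(s$start) else
          s$start[-1L] - s$end[-nrow(s)]
        grp <- cumsum(c(1L, as.integer(gap > span)))
      } else grp <- 1L
      for (g in split(seq_len(nrow(s)), grp)) {
        if (length(g) < min_windows) next
        recs[[length(recs) + 1L]] <- data.frame(
          chrom = s$chrom[g[1L]], start = s$start[g[1L]],
          end = s$end[g[length(g)]], direction = s$direction[g[1L]],
          n_sig_windows = length(g), min_adj_p = min(s$adj_p[g]),
          contrast = contrast, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               direction = character(), n_sig_windows = integer(),
               min_adj_p = numeric(), contrast = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dmr_set", "data.frame")
  out
}

#' Call DMRs from a normalized window matrix
#'
#' End-to-end window-level stage: moderated model fit, BH correction and
#' knitting.
#'
#' @inheritParams dmr_fit
#' @inheritParams knit_dmrs
#' @return A `dmr_set` with the underlying `dmr_fit` attached as attribute
#'   `"fit"`.
#' @export
call_dmrs <- function(wm, design, alpha = 0.01, span = 500L,
                      min_windows = 3L, anchor = c("start", "end")) {
  fit <- dmr_fit(wm, design)
  dmrs <- knit_dmrs(fit, alpha = alpha, span = span,
                    min_windows = min_windows, anchor = anchor)
  attr(dmrs, "fit") <- fit
  dmrs
}

#' @export
print.dmr_set <- function(x, ...) {
  cat("<dmr_set> ", nrow(x), " DMRs (",
      sum(x$direction == "hyper"), " hyper, ",
      sum(x$direction == "hypo"), " hypo)\n", sep = "")
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("  ... and ", nrow(x) - 10L, " more\n", sep = "")
  invisible(x)
}
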