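#' Coverage tracks
#'
#' A coverage track stores per-base read depth for one sample as a
#' run-length-encoded vector per chromosome ([S4Vectors::Rle]), the natural
#' representation for enrichment-sequencing pileups.
#'
#' @param depths Named list (by chromosome) of integer/numeric vectors or
#'   [S4Vectors::Rle] objects of per-base depth.
#' @param seqlengths Named integer vector of chromosome lengths; defaults to
#'   the length of each depth vector.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(depths, seqlengths = NULL) {
  if (length(depths) &&
      (is.null(names(depths)) || anyDuplicated(names(depths))))
    stop("depths must be a uniquely named list of per-chromosome vectors")
  rles <- lapply(depths, function(d) {
    r <- if (methods::is(d, "Rle")) d else S4Vectors::Rle(d)
    if (any(S4Vectors::runValue(r) < 0)) stop("coverage depths must be >= 0")
    r
  })
  if (is.null(seqlengths)) {
    seqlengths <- vapply(rles, length, 1L)
  } else {
    if (!all(names(rles) %in% names(seqlengths)))
      stop("seqlengths missing for some chromosomes")
    seqlengths <- seqlengths[names(rles)]
    bad <- vapply(rles, length, 1L) > seqlengths
    if (any(bad)) stop("coverage extends past declared chromosome length")
    # pad with zeros to declared length
    rles <- mapply(function(r, sl) {
      if (length(r) < sl) c(r, S4Vectors::Rle(0L, sl - length(r))) else r
    }, rles, seqlengths, SIMPLIFY = FALSE)
  }
  structure(list(rle = rles, seqlengths = seqlengths),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("<coverage_track> ", length(x$rle), " chromosome(s), ",
      sum(as.numeric(x$seqlengths)), " bp\n", sep = "")
  for (ch in names(x$rle)) {
    r <- x$rle[[ch]]
    cat("  ", ch, ": length ", length(r), ", mean depth ",
        format(mean(r), digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Build a coverage track from sequenced-fragment intervals
#'
#' Depth is the pileup of fragment intervals, exactly what peak finding
#' consumes.
#'
#' @param fragments Interval data frame of fragments (0-based half-open).
#' @param seqlengths Named integer vector of chromosome lengths.
#' @return A `coverage_track`.
#' @export
coverage_from_fragments <- function(fragments, seqlengths) {
  if (is.null(names(seqlengths))) stop("seqlengths must be named")
  rles <- lapply(names(seqlengths), function(ch) {
    f <- fragments[fragments$chrom == ch, , drop = FALSE]
    if (nrow(f) == 0L) return(S4Vectors::Rle(0L, seqlengths[[ch]]))
    IRanges::coverage(as_iranges(f), width = seqlengths[[ch]])
  })
  names(rles) <- names(seqlengths)
  coverage_track(rles, seqlengths)
}

#' Mean read depth of a track over a set of windows
#'
#' @param track A `coverage_track`.
#' @param windows Interval data frame of windows.
#' @return Numeric vector of per-window mean depth (sum of per-base depth
#'   divided by window length), in window order.
#' @export
mean_depth <- function(track, windows) {
  if (nrow(windows) == 0L) return(numeric(0))
  out <- numeric(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    r <- track$rle[[ch]]
    if (is.null(r)) stop("chromosome ", ch, " absent from coverage track")
    w <- windows[wi, , drop = FALSE]
    if (any(w$start < 0) || any(w$end > length(r)))
      stop("window outside chromosome bounds on ", ch)
    v <- IRanges::Views(r, start = w$start + 1L, end = w$end)
    out[wi] <- IRanges::viewMeans(v)
  }
  out
}
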