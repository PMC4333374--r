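# Readers and writers for the interchange formats. Coordinates are converted
# to/from the internal 0-based half-open convention at these boundaries only.
# Readers are strict: malformed input raises an error naming the line.

#' Read a BEDGraph file into coverage tracks
#'
#' @param path Path to a 4-column BEDGraph file (chrom, start, end, depth).
#'   Records may be unsorted; overlapping records are an error.
#' @param seqlengths Optional named chromosome lengths; defaults to the
#'   maximum end seen per chromosome.
#' @return A `coverage_track`.
#' @export
read_bedgraph <- function(path, seqlengths = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    if (is.null(seqlengths)) seqlengths <- integer(0)
    return(coverage_track(stats::setNames(
      lapply(seqlengths, function(sl) S4Vectors::Rle(0L, sl)),
      names(seqlengths)), seqlengths))
  }
  fields <- strsplit(lines, "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("malformed BEDGraph line ", which(nf != 4L)[1L], " in ", path)
  m <- matrix(unlist(fields), ncol = 4L, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  depth <- suppressWarnings(as.numeric(m[, 4L]))
  bad <- which(is.na(start) | is.na(end) | is.na(depth))
  if (length(bad)) stop("malformed BEDGraph line ", bad[1L], " in ", path)
  if (any(end <= start)) stop("BEDGraph record with end <= start in ", path)
  df <- data.frame(chrom = m[, 1L], start = start, end = end, depth = depth,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  if (is.null(seqlengths)) {
    seqlengths <- vapply(split(df$end, df$chrom), max, numeric(1))
    storage.mode(seqlengths) <- "integer"
  }
  rles <- lapply(names(seqlengths), function(ch) {
    b <- df[df$chrom == ch, , drop = FALSE]
    sl <- seqlengths[[ch]]
    if (nrow(b) == 0L) return(S4Vectors::Rle(0, sl))
    if (nrow(b) > 1L && any(b$start[-1L] < b$end[-nrow(b)]))
      stop("overlapping BEDGraph records on ", ch, " in ", path)
    if (max(b$end) > sl) stop("BEDGraph record past end of ", ch)
    # fill gaps with zero depth
    starts <- c(0, b$end)
    ends <- c(b$start, sl)
    gaps <- data.frame(start = starts, end = ends, depth = 0)
    gaps <- gaps[gaps$end > gaps$start, , drop = FALSE]
    all <- rbind(b[c("start", "end", "depth")], gaps)
    all <- all[order(all$start), , drop = FALSE]
    S4Vectors::Rle(all$depth, all$end - all$start)
  })
  names(rles) <- names(seqlengths)
  coverage_track(rles, seqlengths)
}

#' Write a coverage track as BEDGraph
#'
#' Zero-depth runs are omitted, so `write_bedgraph()` followed by
#' [read_bedgraph()] round-trips the track exactly.
#'
#' @param track A `coverage_track`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$rle)) {
    r <- track$rle[[ch]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r)
    val <- S4Vectors::runValue(r)
    keep <- val != 0
    if (!any(keep)) next
    writeLines(paste(ch, starts[keep], ends[keep], val[keep], sep = "\t"),
               con)
  }
  invisible(path)
}

#' Read / write BED interval files
#'
#' `read_bed()` accepts 3+ column BED; columns 4-6 become `id`, `score`,
#' `strand` when present. `write_bed()` writes whichever of those columns the
#' data frame carries.
#'
#' @param path File path.
#' @return `read_bed()`: an interval data frame.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#)", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 3L)) stop("malformed BED line ", which(nf < 3L)[1L])
  n <- min(nf)
  get <- function(i) vapply(fields, `[[`, "", i)
  out <- data.frame(chrom = get(1L),
                    start = as.numeric(get(2L)),
                    end = as.numeric(get(3L)),
                    stringsAsFactors = FALSE)
  if (any(is.na(out$start) | is.na(out$end))) stop("non-numeric BED coordinates")
  if (any(out$end <= out$start)) stop("BED record with end <= start")
  if (n >= 4L) out$id <- get(4L)
  if (n >= 5L) out$score <- suppressWarnings(as.numeric(get(5L)))
  if (n >= 6L) out$strand <- get(6L)
  out
}

#' @rdname read_bed
#' @param bed Interval data frame.
#' @export
write_bed <- function(bed, path) {
  cols <- list(bed$chrom, format(bed$start, scientific = FALSE, trim = TRUE),
               format(bed$end, scientific = FALSE, trim = TRUE))
  if (!is.null(bed$id)) {
    cols <- c(cols, list(bed$id))
    if (!is.null(bed$score)) {
      cols <- c(cols, list(bed$score))
      if (!is.null(bed$strand)) cols <- c(cols, list(bed$strand))
    }
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read / write FASTA genome sequences
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()].
#'
#' @param path File path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_fasta
#' @param seqs A named [Biostrings::DNAStringSet] or character vector.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Extracts `gene` and `exon` features. GFF 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention (a gene at GFF
#' 1..100 becomes `[0, 100)`).
#'
#' @param path Path to a GFF3 file.
#' @return A `gene_annotation`: list with `genes` (chrom, start, end, strand,
#'   id) and `exons` (chrom, start, end, gene_id) data frames.
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t")
  nf <- lengths(fields)
  if (any(nf != 9L)) stop("malformed GFF line ", which(nf != 9L)[1L])
  get <- function(i) vapply(fields, `[[`, "", i)
  type <- get(3L)
  start1 <- as.numeric(get(4L))
  end1 <- as.numeric(get(5L))
  if (any(is.na(start1) | is.na(end1)) || any(end1 < start1))
    stop("invalid GFF coordinates")
  attr_field <- get(9L)
  attr_get <- function(key) {
    vapply(regmatches(attr_field,
                      gregexpr(paste0("(^|;)", key, "=[^;]*"), attr_field)),
           function(x) {
             if (length(x)) sub(paste0(".*", key, "="), "", x[1L])
             else NA_character_
           }, "")
  }
  ids <- attr_get("ID")
  parents <- attr_get("Parent")
  gi <- type == "gene"
  ei <- type == "exon"
  genes <- data.frame(chrom = get(1L)[gi], start = start1[gi] - 1,
                      end = end1[gi], strand = get(7L)[gi],
                      id = ids[gi], stringsAsFactors = FALSE)
  if (any(is.na(genes$id))) stop("gene feature without ID attribute")
  exons <- data.frame(chrom = get(1L)[ei], start = start1[ei] - 1,
                      end = end1[ei], gene_id = parents[ei],
                      stringsAsFactors = FALSE)
  if (any(is.na(exons$gene_id))) stop("exon feature without Parent attribute")
  gene_annotation(genes, exons)
}

#' Assemble a gene annotation object
#'
#' @param genes Data frame with chrom, start, end, strand (`+`/`-`), id
#'   (0-based half-open).
#' @param exons Data frame with chrom, start, end, gene_id.
#' @return A `gene_annotation` list.
#' @export
gene_annotation <- function(genes, exons) {
  stopifnot(all(c("chrom", "start", "end", "strand", "id") %in% names(genes)),
            all(c("chrom", "start", "end", "gene_id") %in% names(exons)))
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  orphan <- setdiff(genes$id, exons$gene_id)
  if (length(orphan))
    stop("gene(s) with no exons: ", paste(orphan, collapse = ", "))
  structure(list(genes = genes, exons = exons), class = "gene_annotation")
}

#' Read a sample sheet
#'
#' @param path Tab-separated file with a header; must contain `sample_id` plus
#'   every column named in `required_vars`.
#' @param required_vars Biological variables that must be present.
#' @return Data frame of samples.
#' @export
read_sample_sheet <- function(path,
                              required_vars = c("region", "individual", "sex")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("sample_id", required_vars)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sample sheet missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in sample sheet")
  if (any(!nzchar(as.matrix(df[need])) | is.na(df[need])))
    stop("sample sheet contains empty values in required columns")
  df
}

#' Write DMR calls as BED6+
#'
#' Columns: chrom, start, end, contrast, score (-10*log10 of the minimum
#' adjusted P), strand (.), direction, number of significant windows.
#'
#' @param dmrs A `dmr_set` or compatible data frame.
#' @param path Output path.
#' @export
write_dmrs <- function(dmrs, path) {
  score <- round(-10 * log10(pmax(dmrs$min_adj_p, 1e-300)), 2)
  writeLines(paste(dmrs$chrom,
                   format(dmrs$start, scientific = FALSE, trim = TRUE),
                   format(dmrs$end, scientific = FALSE, trim = TRUE),
                   dmrs$contrast, score, ".",
                   dmrs$direction, dmrs$n_sig_windows, sep = "\t"),
             path)
  invisible(path)
}
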