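#' Construct a genomic-interval table
#'
#' Intervals are plain data frames with 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive), the convention used throughout the
#' package and by the BED format.
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive starts.
#' @param end Integer vector, exclusive ends.
#' @param name Optional character vector of interval names.
#' @param strand Optional strand vector (`+`, `-` or `.`).
#' @return A `data.frame` with columns `chrom`, `start`, `end` and, when
#'   supplied, `name` and `strand`.
#' @examples
#' genomic_intervals("chr1", 0L, 100L)
#' @export
genomic_intervals <- function(chrom, start, end, name = NULL, strand = NULL) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(start),
                  end = as.integer(end),
                  stringsAsFactors = FALSE)
  if (!is.null(name)) x$name <- as.character(name)
  if (!is.null(strand)) x$strand <- as.character(strand)
  validate_intervals(x)
  x
}

validate_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  bad <- which(!(x$start >= 0 & x$start < x$end) | is.na(x$chrom) |
                 !nzchar(x$chrom))
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: require 0 <= start < end, chrom non-empty",
                 what, bad[1]), call. = FALSE)
  }
  invisible(x)
}

# 0-based half-open data.frame -> GRanges (1-based closed), and back.
as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

interval_key <- function(x) {
  sprintf("%s:%d-%d", x$chrom, x$start, x$end)
}

#' Read a BED file of genomic intervals
#'
#' Coordinates are taken verbatim as 0-based half-open; input order is
#' preserved. Malformed lines (wrong column count, `start >= end`) raise an
#' error naming the offending line.
#'
#' @param path Path to a tab-separated BED file.
#' @param format `"BED3"` or `"BED6"` (BED6 adds name, score, strand).
#' @return Interval `data.frame` (see [genomic_intervals()]); BED6 input adds
#'   `name`, `score`, `strand` columns.
#' @export
read_intervals <- function(path, format = c("BED3", "BED6")) {
  format <- match.arg(format)
  ncol_want <- if (format == "BED3") 3L else 6L
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    if (format == "BED6") {
      out$name <- character(); out$score <- numeric(); out$strand <- character()
    }
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != ncol_want)) {
    i <- which(nf != ncol_want)[1]
    stop(sprintf("%s line %d: expected %d columns, found %d",
                 path, i, ncol_want, nf[i]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  start <- suppressWarnings(as.integer(m[, 2]))
  end <- suppressWarnings(as.integer(m[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("%s line %d: malformed interval (need 0 <= start < end)",
                 path, bad[1]), call. = FALSE)
  }
  out <- data.frame(chrom = m[, 1], start = start, end = end,
                    stringsAsFactors = FALSE)
  if (format == "BED6") {
    out$name <- m[, 4]
    out$score <- suppressWarnings(as.numeric(m[, 5]))
    out$strand <- m[, 6]
  }
  out
}

#' Write intervals as BED
#'
#' Inverse of [read_intervals()]: a read-write-read cycle is the identity.
#'
#' @param x Interval `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path) {
  validate_intervals(x)
  cols <- c("chrom", "start", "end")
  if (all(c("name", "score", "strand") %in% names(x))) {
    cols <- c(cols, "name", "score", "strand")
  }
  utils::write.table(x[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
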