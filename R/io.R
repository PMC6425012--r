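ibed_cols <- c("bait_chr", "bait_start", "bait_end", "bait_name",
               "oe_chr", "oe_start", "oe_end", "oe_name",
               "N_reads", "score")

#' Read an ibed-style interaction table
#'
#' Ten tab-separated columns: bait anchor (chrom, start, end, name), other-end
#' anchor (chrom, start, end, name), read count and interaction score. A
#' header line starting with `bait_chr` is skipped. Coordinates are 0-based
#' half-open, as written by [write_interactions()].
#'
#' @param path Path to the interaction file.
#' @return `data.frame` with the ten ibed columns; `N_reads` integer, `score`
#'   numeric.
#' @export
read_interactions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  offset <- 0L
  if (length(lines) && startsWith(lines[1], "bait_chr")) {
    lines <- lines[-1]
    offset <- 1L
  }
  if (!length(lines)) {
    out <- data.frame(matrix(nrow = 0, ncol = 10))
    names(out) <- ibed_cols
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 10L)) {
    i <- which(nf != 10L)[1]
    stop(sprintf("%s line %d: expected 10 columns, found %d",
                 path, i + offset, nf[i]), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  score <- suppressWarnings(as.numeric(m[, 10]))
  if (anyNA(score)) {
    i <- which(is.na(score))[1]
    stop(sprintf("%s line %d: non-numeric score '%s'",
                 path, i + offset, m[i, 10]), call. = FALSE)
  }
  data.frame(bait_chr = m[, 1],
             bait_start = as.integer(m[, 2]),
             bait_end = as.integer(m[, 3]),
             bait_name = m[, 4],
             oe_chr = m[, 5],
             oe_start = as.integer(m[, 6]),
             oe_end = as.integer(m[, 7]),
             oe_name = m[, 8],
             N_reads = as.integer(m[, 9]),
             score = score,
             stringsAsFactors = FALSE)
}

#' Write an ibed-style interaction table
#'
#' @param x `data.frame` with the ten ibed columns (see
#'   [read_interactions()]).
#' @param path Output path.
#' @param header Write the column-name header line?
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path, header = TRUE) {
  stopifnot(all(ibed_cols %in% names(x)))
  utils::write.table(x[, ibed_cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = header)
  invisible(path)
}

#' Write interactions as a WashU longrange track
#'
#' Emits the WashU EpiGenome Browser `longrange` text format: one record per
#' anchor per pair, i.e. each cis pair appears twice (once anchored at each
#' end) with the partner written as `chrom2:start2-end2,score`.
#'
#' @param x Interaction `data.frame` with ibed anchor columns and `score`, or
#'   a `v2g_links` object (its supporting interactions are written).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_longrange <- function(x, path) {
  if (inherits(x, "v2g_links")) x <- attr(x, "interactions")
  if (!nrow(x)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  fwd <- sprintf("%s\t%d\t%d\t%s:%d-%d,%s",
                 x$bait_chr, x$bait_start, x$bait_end,
                 x$oe_chr, x$oe_start, x$oe_end, format(x$score, trim = TRUE))
  rev <- sprintf("%s\t%d\t%d\t%s:%d-%d,%s",
                 x$oe_chr, x$oe_start, x$oe_end,
                 x$bait_chr, x$bait_start, x$bait_end, format(x$score, trim = TRUE))
  writeLines(c(rbind(fwd, rev)), path)
  invisible(path)
}

#' Read a TSS annotation table
#'
#' Simple tab-separated gene model: columns `chrom`, `tss` (1-based),
#' `strand`, `gene_id`, `symbol`, `biotype`, one row per TSS (genes with
#' alternative promoters occupy several rows).
#'
#' @param path Path to the TSV (header required).
#' @return `data.frame` with those six columns.
#' @export
read_tss <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "tss", "strand", "gene_id", "symbol", "biotype")
  if (!all(need %in% names(x))) {
    stop("TSS table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x$tss <- as.integer(x$tss)
  if (any(x$tss < 1)) stop("TSS positions are 1-based (>= 1)", call. = FALSE)
  x[, need]
}

#' Write a TSS annotation table
#' @param x TSS `data.frame` (see [read_tss()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract a TSS table from a GTF subset
#'
#' Convenience reader that keeps only transcript records and derives the TSS
#' from the strand (start on `+`, end on `-`). Only the fields the analysis
#' needs are retained.
#'
#' @param path Path to a GTF file (may contain `#` comment lines).
#' @return TSS `data.frame` as from [read_tss()].
#' @export
read_gtf_tss <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(parts, function(p) length(p) >= 9 && p[3] == "transcript",
                 logical(1))
  parts <- parts[keep]
  if (!length(parts)) {
    return(data.frame(chrom = character(), tss = integer(), strand = character(),
                      gene_id = character(), symbol = character(),
                      biotype = character(), stringsAsFactors = FALSE))
  }
  attr1 <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(sprintf('%s "[^"]*"', key), attrs))
    if (!length(m)) return(NA_character_)
    sub(sprintf('%s "([^"]*)"', key), "\\1", m)
  }
  rows <- lapply(parts, function(p) {
    strand <- p[7]
    tss <- if (strand == "-") as.integer(p[5]) else as.integer(p[4])
    data.frame(chrom = p[1], tss = tss, strand = strand,
               gene_id = attr1(p[9], "gene_id"),
               symbol = attr1(p[9], "gene_name"),
               biotype = attr1(p[9], "gene_biotype"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  unique(out)
}

#' Read a proxy-SNP table
#'
#' Comma-separated table with columns `sentinel_id`, `proxy_id`, `r2`,
#' `population`, `gwas_set`, the rAggr-style alternative to computing proxies
#' from a haplotype panel with [find_proxies()].
#'
#' @param path Path to the CSV (header required).
#' @return `data.frame` of proxy records; `r2` numeric in (0, 1].
#' @export
read_proxies <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sentinel_id", "proxy_id", "r2")
  if (!all(need %in% names(x))) {
    stop("proxy table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x$r2 <- as.numeric(x$r2)
  if (any(is.na(x$r2) | x$r2 <= 0 | x$r2 > 1)) {
    stop("proxy r2 values must lie in (0, 1]", call. = FALSE)
  }
  x
}

#' Read a gene-expression table
#'
#' Tab-separated with columns `gene_id`, `symbol`, `fpkm`.
#'
#' @param path Path to the TSV (header required).
#' @return `data.frame` with non-negative `fpkm`.
#' @export
read_expression <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "symbol", "fpkm")
  if (!all(need %in% names(x))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x$fpkm <- as.numeric(x$fpkm)
  if (any(x$fpkm < 0, na.rm = TRUE)) stop("fpkm must be non-negative",
                                          call. = FALSE)
  x[, need]
}

#' Read a phased haplotype panel
#'
#' Tab-separated matrix: one row per haplotype, one column per variant,
#' entries 0/1. Three leading header lines give variant id, chromosome and
#' 1-based position (rows `id`, `chrom`, `pos`), written by
#' [write_haplotypes()].
#'
#' @param path Path to the panel TSV.
#' @return A `haplotype_panel` object: list with `variants` (`data.frame`
#'   `id`, `chrom`, `pos`) and `mat` (haplotypes x variants 0/1 matrix).
#' @export
read_haplotypes <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:3], "\t", fixed = TRUE)
  if (hdr[[1]][1] != "id" || hdr[[2]][1] != "chrom" || hdr[[3]][1] != "pos") {
    stop("haplotype panel must start with 'id', 'chrom', 'pos' header rows",
         call. = FALSE)
  }
  ids <- hdr[[1]][-1]
  variants <- data.frame(id = ids, chrom = hdr[[2]][-1],
                         pos = as.integer(hdr[[3]][-1]),
                         stringsAsFactors = FALSE)
  body <- lines[-(1:3)]
  body <- body[nzchar(body)]
  mat <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE),
                               function(p) as.integer(p)))
  colnames(mat) <- ids
  haplotype_panel(variants, mat)
}

#' Write a phased haplotype panel
#' @param panel A `haplotype_panel`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotypes <- function(panel, path) {
  v <- panel$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste(c("id", v$id), collapse = "\t"),
               paste(c("chrom", v$chrom), collapse = "\t"),
               paste(c("pos", v$pos), collapse = "\t")), con)
  utils::write.table(panel$mat, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load the packaged 46-locus results table
#'
#' Parses the packaged transcription of the published table of implicated
#' target genes at bone-mineral-density GWAS loci: one row per locus with its
#' sentinel SNP, the open-chromatin proxy SNPs looping to an open promoter
#' (with r2 to the sentinel), the implicated genes (with FPKM, `NA` when not
#' quantified) and which GWAS set (DEXA, Heel, Both) the locus came from.
#'
#' @param path Path to the fixture; defaults to the copy shipped with the
#'   package.
#' @return A `table1` object: `data.frame` with columns `locus`, `sentinel`,
#'   `gwas_set` and list-columns `proxies` (`data.frame` `proxy_id`, `r2`) and
#'   `genes` (`data.frame` `symbol`, `fpkm`).
#' @export
load_table1 <- function(path = table1_path()) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("locus", "sentinel", "proxies", "genes", "gwas_set")
  stopifnot(all(need %in% names(x)))
  if (anyDuplicated(x[, c("locus", "sentinel")])) {
    stop("duplicate locus+sentinel rows in table", call. = FALSE)
  }
  parse_pairs <- function(s, val_name) {
    items <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(items, "|", fixed = TRUE)
    id <- vapply(kv, `[`, "", 1)
    val <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2)))
    out <- data.frame(id = id, val = val, stringsAsFactors = FALSE)
    names(out) <- val_name
    out
  }
  x$proxies <- lapply(x$proxies, parse_pairs, c("proxy_id", "r2"))
  x$genes <- lapply(x$genes, parse_pairs, c("symbol", "fpkm"))
  for (i in seq_len(nrow(x))) {
    p <- x$proxies[[i]]
    if (!nrow(p) || !nrow(x$genes[[i]])) {
      stop(sprintf("row %d: proxies and genes must be non-empty", i),
           call. = FALSE)
    }
    if (any(is.na(p$r2) | p$r2 <= 0 | p$r2 > 1)) {
      stop(sprintf("row %d: r2 outside (0,1]", i), call. = FALSE)
    }
  }
  class(x) <- c("table1", class(x))
  x
}

#' Path to the packaged results-table fixture
#' @return File path of the table transcription shipped in `inst/extdata`.
#' @export
table1_path <- function() {
  system.file("extdata", "table1.tsv", package = "capv2g", mustWork = TRUE)
}

#' Flatten the results table to link-shaped rows
#'
#' Expands the per-locus table into one row per (proxy, gene) pair, the shape
#' produced by [map_variants_to_genes()], so that [summarize_loci()] can be
#' applied to it directly.
#'
#' @param t1 A `table1` object from [load_table1()].
#' @return `data.frame` with columns `locus`, `sentinel_id`, `proxy_id`, `r2`,
#'   `symbol`, `fpkm`, `gwas_set`.
#' @export
table1_links <- function(t1) {
  rows <- lapply(seq_len(nrow(t1)), function(i) {
    p <- t1$proxies[[i]]
    g <- t1$genes[[i]]
    grid <- expand.grid(pi = seq_len(nrow(p)), gi = seq_len(nrow(g)))
    data.frame(locus = t1$locus[i], sentinel_id = t1$sentinel[i],
               proxy_id = p$proxy_id[grid$pi], r2 = p$r2[grid$pi],
               symbol = g$symbol[grid$gi], fpkm = g$fpkm[grid$gi],
               gwas_set = t1$gwas_set[i], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
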