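#' In-silico restriction digestion of a genome
#'
#' Digests each chromosome with a short recognition site (default `GATC`, the
#' DpnII site used by high-resolution 4-cutter Capture C designs). A cut is
#' placed at the 0-based start index of every occurrence of the site,
#' case-insensitively; a cut at index 0 is a no-op. Fragment boundaries are
#' the sorted cut positions plus the chromosome ends, so fragments tile each
#' chromosome exactly.
#'
#' @param sequences Named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences.
#' @param site Recognition site (non-empty string over A/C/G/T).
#' @return A `fragment_map`: `data.frame` with columns `chrom`, `start`,
#'   `end` (0-based half-open) and `frag_id` (globally unique, ascending in
#'   genome order), with chromosome lengths in `attr(, "seqlengths")`.
#' @examples
#' digest_genome(c(chrA = "ACGATCGT"))
#' @export
digest_genome <- function(sequences, site = "GATC") {
  stopifnot(nzchar(site))
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- as.character(sequences)
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named by chromosome", call. = FALSE)
  }
  site <- toupper(site)
  out <- vector("list", length(sequences))
  seqlen <- integer(length(sequences))
  for (i in seq_along(sequences)) {
    chrom <- names(sequences)[i]
    len <- nchar(sequences[[i]])
    seqlen[i] <- len
    if (len == 0L) {
      warning(sprintf("chromosome %s is empty; zero fragments", chrom),
              call. = FALSE)
      out[[i]] <- data.frame(chrom = character(), start = integer(),
                             end = integer(), stringsAsFactors = FALSE)
      next
    }
    s <- Biostrings::DNAString(toupper(sequences[[i]]))
    hits <- Biostrings::matchPattern(site, s)
    cuts <- Biostrings::start(hits) - 1L  # 0-based site start
    cuts <- sort(unique(cuts[cuts > 0L & cuts < len]))
    bounds <- c(0L, cuts, len)
    out[[i]] <- data.frame(chrom = chrom,
                           start = bounds[-length(bounds)],
                           end = bounds[-1],
                           stringsAsFactors = FALSE)
  }
  fm <- do.call(rbind, out)
  fm$frag_id <- seq_len(nrow(fm))
  names(seqlen) <- names(sequences)
  attr(fm, "seqlengths") <- seqlen
  attr(fm, "site") <- site
  class(fm) <- c("fragment_map", "data.frame")
  fm
}

#' @export
print.fragment_map <- function(x, ...) {
  sizes <- x$end - x$start
  cat(sprintf("fragment_map: %d fragments on %d chromosome(s) (site %s)\n",
              nrow(x), length(unique(x$chrom)), attr(x, "site")))
  if (nrow(x)) {
    cat(sprintf("  fragment size: mean %.1f bp, median %.1f bp\n",
                mean(sizes), stats::median(sizes)))
  }
  invisible(x)
}

#' Summary statistics of a fragment map
#' @param object A `fragment_map`.
#' @param ... Unused.
#' @return List with `n_fragments`, `mean_size`, `median_size`,
#'   `per_chromosome` counts.
#' @export
summary.fragment_map <- function(object, ...) {
  sizes <- object$end - object$start
  list(n_fragments = nrow(object),
       mean_size = mean(sizes),
       median_size = stats::median(sizes),
       per_chromosome = table(object$chrom))
}

#' Group consecutive fragments into bins
#'
#' Reproduces the artificial lower-resolution map used to call longer-range
#' interactions: per chromosome, consecutive runs of `k` restriction
#' fragments form one bin (the last bin per chromosome may be smaller). Bins
#' never span chromosomes.
#'
#' @param fm A `fragment_map` from [digest_genome()].
#' @param k Fragments per bin (default 4).
#' @return A `bin_map`: `data.frame` with `chrom`, `start`, `end`, `bin_id`,
#'   `first_frag`, `last_frag` (member fragments are the contiguous id run
#'   `first_frag:last_frag`).
#' @export
bin_fragments <- function(fm, k = 4L) {
  stopifnot(k >= 1)
  k <- as.integer(k)
  chroms <- unique(fm$chrom)
  out <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    f <- fm[fm$chrom == chroms[i], , drop = FALSE]
    grp <- (seq_len(nrow(f)) - 1L) %/% k
    first <- !duplicated(grp)
    last <- !duplicated(grp, fromLast = TRUE)
    out[[i]] <- data.frame(chrom = chroms[i],
                           start = f$start[first],
                           end = f$end[last],
                           first_frag = f$frag_id[first],
                           last_frag = f$frag_id[last],
                           stringsAsFactors = FALSE)
  }
  bm <- do.call(rbind, out)
  bm$bin_id <- seq_len(nrow(bm))
  attr(bm, "k") <- k
  attr(bm, "seqlengths") <- attr(fm, "seqlengths")
  class(bm) <- c("bin_map", "data.frame")
  bm
}

#' Locate the fragment containing a position
#'
#' Binary-search lookup (via `findInterval`) of the unique fragment covering
#' each 0-based position.
#'
#' @param fm A `fragment_map` (or `bin_map`).
#' @param chrom Chromosome name(s), recycled against `pos0`.
#' @param pos0 0-based position(s) within the chromosome.
#' @return Integer vector of `frag_id` (or `bin_id`).
#' @export
locate_fragment <- function(fm, chrom, pos0) {
  n <- max(length(chrom), length(pos0))
  chrom <- rep_len(as.character(chrom), n)
  pos0 <- rep_len(as.integer(pos0), n)
  id_col <- if (inherits(fm, "bin_map")) "bin_id" else "frag_id"
  out <- integer(n)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    f <- fm[fm$chrom == ch, , drop = FALSE]
    if (!nrow(f)) stop(sprintf("unknown chromosome '%s'", ch), call. = FALSE)
    p <- pos0[idx]
    if (any(p < f$start[1] | p >= f$end[nrow(f)])) {
      stop(sprintf("position out of range on %s", ch), call. = FALSE)
    }
    out[idx] <- f[[id_col]][findInterval(p, f$start)]
  }
  out
}

#' Design promoter baits on a fragment map
#'
#' A fragment is baited if and only if it overlaps the window
#' `[tss - window, tss + window]` around some annotated TSS (point
#' containment when `window = 0`). One fragment may serve several genes
#' (shared promoters) and one gene several fragments (alternative
#' promoters).
#'
#' @param fm A `fragment_map`.
#' @param genes TSS table as from [read_tss()].
#' @param window Half-width in bp of the promoter window around each TSS.
#' @return A `bait_map`: `data.frame` with one row per (bait fragment, gene,
#'   TSS) with columns `frag_id`, `chrom`, `start`, `end`, `gene_id`,
#'   `symbol`, `tss`.
#' @export
design_baits <- function(fm, genes, window = 0L) {
  stopifnot(nrow(genes) > 0)
  unknown <- setdiff(unique(genes$chrom), unique(fm$chrom))
  if (length(unknown)) {
    off <- genes$gene_id[genes$chrom %in% unknown]
    stop("TSS on unknown chromosome for gene(s): ",
         paste(unique(off), collapse = ", "), call. = FALSE)
  }
  window <- as.integer(window)
  # promoter window in 0-based half-open coords
  w <- data.frame(chrom = genes$chrom,
                  start = pmax(0L, genes$tss - 1L - window),
                  end = genes$tss + window,
                  stringsAsFactors = FALSE)
  hits <- GenomicRanges::findOverlaps(as_granges(w), as_granges(fm))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  bm <- data.frame(frag_id = fm$frag_id[si],
                   chrom = fm$chrom[si],
                   start = fm$start[si],
                   end = fm$end[si],
                   gene_id = genes$gene_id[qi],
                   symbol = genes$symbol[qi],
                   tss = genes$tss[qi],
                   stringsAsFactors = FALSE)
  bm <- bm[order(bm$frag_id, bm$gene_id, bm$tss), , drop = FALSE]
  rownames(bm) <- NULL
  class(bm) <- c("bait_map", "data.frame")
  bm
}

#' @export
print.bait_map <- function(x, ...) {
  cat(sprintf("bait_map: %d bait fragments covering %d gene(s), %d TSS\n",
              length(unique(x$frag_id)), length(unique(x$gene_id)),
              nrow(unique(x[, c("gene_id", "tss")]))))
  invisible(x)
}

#' Write a fragment or bin map in rmap format
#'
#' Tab-separated `chrom`, `start`, `end`, `id` with 1-based starts (the
#' CHiCAGO rmap convention); [read_rmap()] inverts the conversion.
#'
#' @param fm `fragment_map` or `bin_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rmap <- function(fm, path) {
  id_col <- if (inherits(fm, "bin_map")) "bin_id" else "frag_id"
  out <- data.frame(chrom = fm$chrom, start = fm$start + 1L, end = fm$end,
                    id = fm[[id_col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an rmap file back to a fragment map
#' @param path Path written by [write_rmap()].
#' @return `fragment_map` (0-based half-open coordinates restored).
#' @export
read_rmap <- function(path) {
  x <- utils::read.delim(path, header = FALSE,
                         col.names = c("chrom", "start", "end", "frag_id"),
                         stringsAsFactors = FALSE)
  x$start <- as.integer(x$start) - 1L
  sl <- tapply(x$end, x$chrom, max)
  attr(x, "seqlengths") <- sl[unique(x$chrom)]
  class(x) <- c("fragment_map", "data.frame")
  x
}

#' Write a baitmap file
#'
#' rmap columns plus a `;`-separated gene-symbol annotation per bait
#' fragment (CHiCAGO baitmap convention, 1-based starts).
#'
#' @param baits `bait_map` from [design_baits()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_baitmap <- function(baits, path) {
  key <- baits$frag_id
  ann <- vapply(split(baits$symbol, key),
                function(s) paste(sort(unique(s)), collapse = ";"), "")
  first <- !duplicated(key)
  out <- data.frame(chrom = baits$chrom[first],
                    start = baits$start[first] + 1L,
                    end = baits$end[first],
                    id = baits$frag_id[first],
                    ann = ann[as.character(baits$frag_id[first])])
  out <- out[order(out$id), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
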