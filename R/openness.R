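#' Annotate regions as open or closed chromatin
#'
#' A region is open if and only if it shares at least 1 bp with an ATAC-seq
#' peak (same chromosome, `max(starts) < min(ends)` in half-open
#' coordinates). Touching intervals do not overlap.
#'
#' @param regions Interval `data.frame` (0-based half-open); an `id` column
#'   is used if present, otherwise a `name` column, otherwise a
#'   `chrom:start-end` key is generated.
#' @param peaks Peak interval `data.frame` (e.g. from [read_intervals()]).
#' @param provenance Identifier of the peak set, stored on the result.
#' @return `data.frame` with columns `id`, `chrom`, `start`, `end`, `open`
#'   (logical), with the peak-set identifier in `attr(, "provenance")`.
#' @export
annotate_openness <- function(regions, peaks, provenance = "peaks") {
  id <- if ("id" %in% names(regions)) as.character(regions$id)
        else if ("name" %in% names(regions)) as.character(regions$name)
        else interval_key(regions)
  open <- if (nrow(regions) == 0 || nrow(peaks) == 0) {
    logical(nrow(regions))
  } else {
    # disjoint chromosome sets are a valid no-overlap case, not a warning
    suppressWarnings(IRanges::overlapsAny(as_granges(regions),
                                          as_granges(peaks)))
  }
  out <- data.frame(id = id, chrom = regions$chrom, start = regions$start,
                    end = regions$end, open = open, stringsAsFactors = FALSE)
  attr(out, "provenance") <- provenance
  out
}

#' Annotate variants as open or closed chromatin
#'
#' A variant is open if its 1-bp interval `[pos - 1, pos)` (0-based, from the
#' 1-based position) overlaps a peak.
#'
#' @param variants `data.frame` with columns `id`, `chrom`, `pos` (1-based).
#' @param peaks Peak interval `data.frame`.
#' @param provenance Identifier of the peak set.
#' @return `data.frame` with columns `id`, `chrom`, `pos`, `open`.
#' @export
variant_openness <- function(variants, peaks, provenance = "peaks") {
  regions <- data.frame(chrom = variants$chrom,
                        start = as.integer(variants$pos) - 1L,
                        end = as.integer(variants$pos),
                        id = variants$id, stringsAsFactors = FALSE)
  ann <- annotate_openness(regions, peaks, provenance)
  data.frame(id = ann$id, chrom = ann$chrom, pos = variants$pos,
             open = ann$open, stringsAsFactors = FALSE)
}

#' Annotate promoter (bait) openness per gene
#'
#' A gene promoter is open if at least one of its baited fragments overlaps a
#' peak. Genes of the annotation that received no bait are marked
#' not-assessable (`open = NA`) with a warning.
#'
#' @param baits `bait_map` from [design_baits()].
#' @param peaks Peak interval `data.frame`.
#' @param genes Optional TSS table; when given, genes absent from the bait
#'   map are reported as not-assessable.
#' @return List with `genes` (`data.frame` `gene_id`, `symbol`, `open`,
#'   `n_baits`) and `baits` (`data.frame` `frag_id`, `open`).
#' @export
promoter_openness <- function(baits, peaks, genes = NULL) {
  first <- !duplicated(baits$frag_id)
  bait_frags <- data.frame(chrom = baits$chrom[first],
                           start = baits$start[first],
                           end = baits$end[first],
                           id = as.character(baits$frag_id[first]),
                           stringsAsFactors = FALSE)
  bann <- annotate_openness(bait_frags, peaks)
  bait_open <- data.frame(frag_id = baits$frag_id[first], open = bann$open)
  open_by_frag <- stats::setNames(bann$open, bann$id)
  per_gene <- split(as.character(baits$frag_id), baits$gene_id)
  gdf <- data.frame(gene_id = names(per_gene),
                    open = vapply(per_gene,
                                  function(f) any(open_by_frag[unique(f)]),
                                  logical(1)),
                    n_baits = vapply(per_gene,
                                     function(f) length(unique(f)), 1L),
                    stringsAsFactors = FALSE)
  sym <- baits$symbol[match(gdf$gene_id, baits$gene_id)]
  gdf <- data.frame(gene_id = gdf$gene_id, symbol = sym, open = gdf$open,
                    n_baits = gdf$n_baits, stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    missing <- setdiff(unique(genes$gene_id), gdf$gene_id)
    if (length(missing)) {
      warning(sprintf("%d gene(s) have no bait; openness not assessable",
                      length(missing)), call. = FALSE)
      add <- data.frame(gene_id = missing,
                        symbol = genes$symbol[match(missing, genes$gene_id)],
                        open = NA, n_baits = 0L, stringsAsFactors = FALSE)
      gdf <- rbind(gdf, add)
    }
  }
  rownames(gdf) <- NULL
  list(genes = gdf, baits = bait_open)
}

#' Export an openness annotation as TSV
#' @param ann Annotation `data.frame` with `id` and `open` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_openness <- function(ann, path) {
  out <- data.frame(id = ann$id, open = as.integer(ann$open))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
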