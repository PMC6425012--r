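#' Map open proxy variants to open promoters through chromatin loops
#'
#' The core inference. A link from proxy variant to gene is emitted when all
#' four predicates hold:
#' \enumerate{
#'   \item the proxy lies in open chromatin (1-bp peak overlap);
#'   \item the proxy's restriction fragment is \emph{not} itself a baited
#'     promoter region;
#'   \item a retained interaction joins the proxy's fragment (or a bin
#'     containing it) to a bait fragment of the gene;
#'   \item the gene's promoter is open (at least one baited fragment overlaps
#'     a peak).
#' }
#' Links are deduplicated at the (locus, proxy, gene) level; all supporting
#' interactions are recorded.
#'
#' @param proxies Proxy `data.frame` with columns `sentinel_id`, `proxy_id`,
#'   `r2`, `chrom`, `pos` (1-based) and optionally `gwas_set` and `locus`
#'   (defaults to the sentinel id).
#' @param peaks Open-chromatin peak intervals.
#' @param fm `fragment_map` on which everything was built.
#' @param baits `bait_map` from [design_baits()].
#' @param ix `interactome` from [merge_resolutions()].
#' @return A `v2g_links` object: `data.frame` with one row per (locus, proxy,
#'   gene) and columns `locus`, `sentinel_id`, `proxy_id`, `r2`, `gwas_set`,
#'   `chrom`, `pos`, `proxy_frag`, `gene_id`, `symbol`, `bait_frags`,
#'   `n_interactions`, `interaction_keys`. The distinct supporting calls are
#'   attached as `attr(, "interactions")`.
#' @export
map_variants_to_genes <- function(proxies, peaks, fm, baits, ix) {
  p <- proxies
  if (!"locus" %in% names(p)) p$locus <- p$sentinel_id
  if (!"gwas_set" %in% names(p)) p$gwas_set <- NA_character_
  p <- p[!duplicated(p[, c("locus", "sentinel_id", "proxy_id")]), ,
         drop = FALSE]
  unknown <- setdiff(unique(p$chrom), unique(fm$chrom))
  if (length(unknown)) {
    stop("fragment-map mismatch: proxy chromosome(s) not on map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  empty <- empty_links(ix[0, , drop = FALSE])
  if (!nrow(p) || !nrow(ix)) return(empty)

  vo <- variant_openness(
    data.frame(id = p$proxy_id, chrom = p$chrom, pos = p$pos), peaks)
  p$open <- vo$open
  p$proxy_frag <- locate_fragment(fm, p$chrom, p$pos - 1L)
  p$in_bait <- p$proxy_frag %in% unique(baits$frag_id)

  prom <- promoter_openness(baits, peaks)
  open_genes <- prom$genes$gene_id[prom$genes$open %in% TRUE]

  # proxy (1-bp point) inside the other-end anchor of a call
  proxy_gr <- GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$pos, p$pos))
  po <- GenomicRanges::findOverlaps(proxy_gr, anchor_gr(ix, "oe"))
  # gene bait fragment inside/overlapping the bait anchor of a call
  bait_gr <- GenomicRanges::GRanges(baits$chrom,
                                    IRanges::IRanges(baits$start + 1L,
                                                     baits$end))
  bg <- GenomicRanges::findOverlaps(anchor_gr(ix, "bait"), bait_gr)

  cand <- merge(
    data.frame(pi = S4Vectors::queryHits(po), ci = S4Vectors::subjectHits(po)),
    data.frame(ci = S4Vectors::queryHits(bg),
               gene_id = baits$gene_id[S4Vectors::subjectHits(bg)],
               symbol = baits$symbol[S4Vectors::subjectHits(bg)],
               bait_frag = baits$frag_id[S4Vectors::subjectHits(bg)]),
    by = "ci")
  if (!nrow(cand)) return(empty)
  keep <- p$open[cand$pi] & !p$in_bait[cand$pi] &
    cand$gene_id %in% open_genes
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(empty)

  ix_key <- sprintf("%s:%d-%d|%s:%d-%d",
                    ix$bait_chr, ix$bait_start, ix$bait_end,
                    ix$oe_chr, ix$oe_start, ix$oe_end)
  grp <- split(cand, paste(cand$pi, cand$gene_id))
  links <- do.call(rbind, lapply(grp, function(g) {
    i <- g$pi[1]
    data.frame(locus = p$locus[i], sentinel_id = p$sentinel_id[i],
               proxy_id = p$proxy_id[i], r2 = p$r2[i],
               gwas_set = p$gwas_set[i], chrom = p$chrom[i], pos = p$pos[i],
               proxy_frag = p$proxy_frag[i],
               gene_id = g$gene_id[1], symbol = g$symbol[1],
               bait_frags = paste(sort(unique(g$bait_frag)), collapse = ";"),
               n_interactions = length(unique(g$ci)),
               interaction_keys = paste(sort(unique(ix_key[g$ci])),
                                        collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  links <- links[order(links$locus, links$proxy_id, links$gene_id), ,
                 drop = FALSE]
  rownames(links) <- NULL
  support <- ix[sort(unique(cand$ci)), , drop = FALSE]
  attr(links, "interactions") <- support
  class(links) <- c("v2g_links", "data.frame")
  links
}

empty_links <- function(support) {
  links <- data.frame(locus = character(), sentinel_id = character(),
                      proxy_id = character(), r2 = numeric(),
                      gwas_set = character(), chrom = character(),
                      pos = integer(), proxy_frag = integer(),
                      gene_id = character(), symbol = character(),
                      bait_frags = character(), n_interactions = integer(),
                      interaction_keys = character(), stringsAsFactors = FALSE)
  attr(links, "interactions") <- support
  class(links) <- c("v2g_links", "data.frame")
  links
}

#' @export
print.v2g_links <- function(x, ...) {
  cat(sprintf("v2g_links: %d links | %d loci, %d proxies, %d genes\n",
              nrow(x), length(unique(x$locus)), length(unique(x$proxy_id)),
              length(unique(x$symbol))))
  invisible(x)
}

#' Classify a locus relative to the sentinel's nearest gene
#'
#' The nearest gene is the annotated gene minimising, over its TSSs, the
#' distance `|TSS - sentinel position|` (ties broken by smaller `gene_id` and
#' reported via `message()`). The locus category is:
#' `nearest_only` when the implicated gene set is exactly the nearest gene;
#' `nearest_and_distant` when the nearest gene is implicated together with
#' others; `distant_only` when the nearest gene is not implicated.
#'
#' @param implicated Character vector of implicated `gene_id`s at the locus
#'   (non-empty).
#' @param genes TSS table ([read_tss()]); all annotated genes on the
#'   sentinel's chromosome are candidates for "nearest".
#' @param sentinel_chrom,sentinel_pos Sentinel SNP location (1-based).
#' @return List with `category` (one of the three labels) and `nearest`
#'   (the nearest `gene_id`).
#' @export
classify_locus <- function(implicated, genes, sentinel_chrom, sentinel_pos) {
  implicated <- unique(implicated)
  if (!length(implicated)) stop("empty implicated gene set", call. = FALSE)
  g <- genes[genes$chrom == sentinel_chrom, , drop = FALSE]
  if (!nrow(g)) stop("no annotated genes on sentinel chromosome",
                     call. = FALSE)
  d <- abs(g$tss - sentinel_pos)
  per_gene <- tapply(d, g$gene_id, min)
  best <- min(per_gene)
  nearest_cands <- sort(names(per_gene)[per_gene == best])
  if (length(nearest_cands) > 1) {
    message(sprintf("nearest-gene tie at %s:%d broken by gene_id: %s",
                    sentinel_chrom, sentinel_pos,
                    paste(nearest_cands, collapse = ", ")))
  }
  nearest <- nearest_cands[1]
  category <- if (identical(sort(implicated), nearest)) {
    "nearest_only"
  } else if (nearest %in% implicated) {
    "nearest_and_distant"
  } else {
    "distant_only"
  }
  list(category = category, nearest = nearest)
}

#' Summarize variant-to-gene links per locus and globally
#'
#' Collapses a link table (from [map_variants_to_genes()] or
#' [table1_links()]) to one row per locus — the shape of the published
#' results table — plus global counts: distinct loci, proxies, genes, open
#' proxy regions, supporting interactions, and the fraction of loci
#' contacting more than one baited promoter region. When a gene annotation
#' and sentinel positions are supplied, each locus is also classified
#' relative to its nearest gene and the category fractions are reported.
#'
#' @param links Link `data.frame` with at least `locus`, `sentinel_id`,
#'   `proxy_id`, `r2`, `symbol`; optionally `gene_id`, `gwas_set`,
#'   `proxy_frag`, `bait_frags`, `interaction_keys`, `fpkm`.
#' @param expression Optional expression table ([read_expression()]) used to
#'   annotate gene FPKM and expression percentile.
#' @param genes Optional TSS table enabling locus classification.
#' @param sentinels Optional `data.frame` (`id`, `chrom`, `pos`) of sentinel
#'   positions, required for classification.
#' @return List of class `locus_summary`: `per_locus` `data.frame` and
#'   `counts` list.
#' @export
summarize_loci <- function(links, expression = NULL, genes = NULL,
                           sentinels = NULL) {
  if (!nrow(links)) stop("no links to summarize", call. = FALSE)
  gene_col <- if ("gene_id" %in% names(links)) "gene_id" else "symbol"
  per <- lapply(split(seq_len(nrow(links)), links$locus), function(i) {
    l <- links[i, , drop = FALSE]
    prox <- l[!duplicated(l$proxy_id), c("proxy_id", "r2"), drop = FALSE]
    gs <- sort(unique(l$symbol))
    n_baited <- if ("bait_frags" %in% names(l)) {
      length(unique(unlist(strsplit(l$bait_frags, ";", fixed = TRUE))))
    } else {
      NA_integer_
    }
    data.frame(locus = l$locus[1], sentinel = l$sentinel_id[1],
               n_proxies = nrow(prox),
               proxies = paste(sprintf("%s (%g)", prox$proxy_id, prox$r2),
                               collapse = ", "),
               n_genes = length(gs),
               genes = paste(gs, collapse = ", "),
               n_baited_regions = n_baited,
               gwas_set = if ("gwas_set" %in% names(l)) l$gwas_set[1]
                          else NA_character_,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL

  if (!is.null(genes) && !is.null(sentinels)) {
    per$category <- vapply(per$locus, function(lc) {
      l <- links[links$locus == lc, , drop = FALSE]
      s <- sentinels[sentinels$id == l$sentinel_id[1], , drop = FALSE]
      if (!nrow(s)) return(NA_character_)
      classify_locus(unique(l[[gene_col]]), genes, s$chrom[1],
                     s$pos[1])$category
    }, "")
  }

  counts <- list(
    n_loci = length(unique(links$locus)),
    n_distinct_proxies = length(unique(links$proxy_id)),
    n_distinct_genes = length(unique(links$symbol)),
    n_distinct_open_regions = if ("proxy_frag" %in% names(links)) {
      length(unique(links$proxy_frag))
    } else NA_integer_,
    n_distinct_interactions = if ("interaction_keys" %in% names(links)) {
      length(unique(unlist(strsplit(links$interaction_keys, ";",
                                    fixed = TRUE))))
    } else NA_integer_,
    n_distinct_baits = if ("bait_frags" %in% names(links)) {
      length(unique(unlist(strsplit(links$bait_frags, ";", fixed = TRUE))))
    } else NA_integer_,
    frac_multi_bait = if (!all(is.na(per$n_baited_regions))) {
      mean(per$n_baited_regions > 1, na.rm = TRUE)
    } else NA_real_)
  if ("category" %in% names(per)) {
    counts$category_fractions <-
      prop.table(table(factor(per$category,
                              levels = c("nearest_only", "nearest_and_distant",
                                         "distant_only"))))
  }
  if (!is.null(expression)) {
    ann <- annotate_expression(unique(links$symbol), expression)
    counts$frac_high_expressed <- mean(ann$high, na.rm = TRUE)
  }
  structure(list(per_locus = per, counts = counts), class = "locus_summary")
}

#' @export
print.locus_summary <- function(x, ...) {
  c0 <- x$counts
  cat(sprintf("locus_summary: %d loci | %d proxies -> %d genes\n",
              c0$n_loci, c0$n_distinct_proxies, c0$n_distinct_genes))
  if (!is.null(c0$category_fractions)) {
    cf <- c0$category_fractions
    cat(sprintf("  categories: nearest_only %.0f%%, nearest_and_distant %.0f%%, distant_only %.0f%%\n",
                100 * cf[["nearest_only"]], 100 * cf[["nearest_and_distant"]],
                100 * cf[["distant_only"]]))
  }
  invisible(x)
}

#' Annotate genes with expression level and percentile
#'
#' The percentile of each gene is its mean-rank percentile among all genes of
#' the expression table: `100 * rank(fpkm, ties = "average") / n`. A gene is
#' flagged highly expressed when its percentile exceeds 50 (strict). Genes
#' absent from the table get `NA` FPKM and an undefined flag.
#'
#' @param genes Character vector of gene identifiers (matched against the
#'   table's `gene_id`, falling back to `symbol`).
#' @param expr_table Expression table ([read_expression()]).
#' @return `data.frame` with columns `gene`, `fpkm`, `percentile`, `high`.
#' @export
annotate_expression <- function(genes, expr_table) {
  pct <- 100 * rank(expr_table$fpkm, ties.method = "average") /
    nrow(expr_table)
  i <- match(genes, expr_table$gene_id)
  j <- match(genes, expr_table$symbol)
  i[is.na(i)] <- j[is.na(i)]
  data.frame(gene = genes,
             fpkm = expr_table$fpkm[i],
             percentile = pct[i],
             high = ifelse(is.na(i), NA, pct[i] > 50),
             stringsAsFactors = FALSE)
}

#' Compare variant-to-gene links between two cell types
#'
#' For every locus present in either link set, compares the (proxy, gene)
#' pair sets and assigns a label: `identical` (equal pair sets),
#' `target_subset` (one pair set a strict subset of the other),
#' `different_proxy_same_target` (shared target genes reached through
#' non-identical pairs), `different_target` (disjoint gene sets), or
#' `absent_in_A` / `absent_in_B`.
#'
#' @param linksA,linksB Link `data.frame`s with `locus`, `proxy_id`,
#'   `symbol` columns.
#' @return `data.frame` with columns `locus`, `label`, `n_pairs_A`,
#'   `n_pairs_B`.
#' @export
compare_celltypes <- function(linksA, linksB) {
  pairs <- function(l, lc) {
    x <- l[l$locus == lc, , drop = FALSE]
    unique(paste(x$proxy_id, x$symbol, sep = "->"))
  }
  genes_of <- function(pp) unique(sub("^.*->", "", pp))
  loci <- sort(unique(c(linksA$locus, linksB$locus)))
  lab <- vapply(loci, function(lc) {
    a <- pairs(linksA, lc)
    b <- pairs(linksB, lc)
    if (!length(a)) return("absent_in_A")
    if (!length(b)) return("absent_in_B")
    if (setequal(a, b)) return("identical")
    if (all(b %in% a) || all(a %in% b)) return("target_subset")
    if (length(intersect(genes_of(a), genes_of(b)))) {
      return("different_proxy_same_target")
    }
    "different_target"
  }, "")
  data.frame(locus = loci, label = lab,
             n_pairs_A = vapply(loci, function(lc) length(pairs(linksA, lc)), 1L),
             n_pairs_B = vapply(loci, function(lc) length(pairs(linksB, lc)), 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write a link table as TSV
#' @param links `v2g_links` or any link `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_links <- function(links, path) {
  utils::write.table(as.data.frame(links), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
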