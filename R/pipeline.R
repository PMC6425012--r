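#' Assemble a pipeline configuration
#'
#' Collects the input paths and tunable constants of the variant-to-gene
#' pipeline. Defaults mirror the study constants: proxy expansion at
#' r2 >= 0.8 (0.4 as the liberal companion), interaction score cutoff 5,
#' 4 fragments per bin.
#'
#' @param genome_fa FASTA of the genome to digest.
#' @param tss_tsv TSS annotation ([read_tss()]).
#' @param peaks_bed Open-chromatin peaks (BED3).
#' @param frag1_ibed,frag4_ibed Interaction calls at 1- and 4-fragment
#'   resolution (ibed).
#' @param proxies_csv Proxy table with positions (columns of
#'   [read_proxies()] plus `chrom`, `pos`, optionally `locus`).
#' @param expression_tsv Optional expression table.
#' @param outdir Output directory.
#' @param r2_threshold,liberal_r2 Proxy r2 thresholds.
#' @param score_threshold Interaction score cutoff.
#' @param bin_size Fragments per bin.
#' @param window_bp Promoter window half-width for bait design.
#' @param seed Seed recorded in the bundle.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome_fa, tss_tsv, peaks_bed, frag1_ibed,
                            frag4_ibed, proxies_csv, expression_tsv = NULL,
                            outdir = tempfile("v2g_out"), r2_threshold = 0.8,
                            liberal_r2 = 0.4, score_threshold = 5,
                            bin_size = 4L, window_bp = 0L, seed = 1L) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1, score_threshold >= 0,
            bin_size >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

log_line <- function(...) message(sprintf(...))

#' Run the full variant-to-gene pipeline
#'
#' Executes digest -> bait design -> proxy ingest -> openness -> interaction
#' load/merge -> variant-to-gene mapping -> locus classification -> summary,
#' writing every stage artifact into `config$outdir` and logging input/output
#' counts per stage. Any stage error aborts with the stage name in the
#' message.
#'
#' @param config A [pipeline_config()].
#' @return The output bundle (list of class `v2g_bundle`): `fragment_map`,
#'   `bins`, `baits`, `interactome`, `stats`, `links`, `summary`, `config`,
#'   `paths` of written artifacts.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(config$outdir, f)

  seqs <- stage("digest", {
    s <- Biostrings::readDNAStringSet(config$genome_fa)
    names(s) <- sub("\\s.*$", "", names(s))
    s
  })
  fm <- stage("digest", digest_genome(seqs))
  log_line("digest: %d fragments on %d chromosomes", nrow(fm),
           length(unique(fm$chrom)))
  write_rmap(fm, p("fragments.rmap"))
  bins <- stage("binning", bin_fragments(fm, config$bin_size))
  write_rmap(bins, p("bins.rmap"))

  genes <- stage("baits", read_tss(config$tss_tsv))
  baits <- stage("baits", design_baits(fm, genes, config$window_bp))
  log_line("baits: %d bait fragments for %d genes",
           length(unique(baits$frag_id)), length(unique(baits$gene_id)))
  write_baitmap(baits, p("baits.baitmap"))

  proxies <- stage("proxies", {
    x <- read_proxies(config$proxies_csv)
    if (!all(c("chrom", "pos") %in% names(x))) {
      stop("proxy table needs chrom and pos columns")
    }
    x[x$r2 >= config$r2_threshold, , drop = FALSE]
  })
  log_line("proxies: %d records at r2 >= %g", nrow(proxies),
           config$r2_threshold)

  peaks <- stage("openness", read_intervals(config$peaks_bed, "BED3"))
  prom <- stage("openness", promoter_openness(baits, peaks, genes))
  vo <- stage("openness", variant_openness(
    data.frame(id = proxies$proxy_id, chrom = proxies$chrom,
               pos = proxies$pos), peaks))
  log_line("openness: %d/%d proxies open; %d/%d promoters open",
           sum(vo$open), nrow(vo), sum(prom$genes$open %in% TRUE),
           nrow(prom$genes))
  write_openness(vo, p("proxy_openness.tsv"))

  ix <- stage("interactions", {
    c1 <- load_calls(read_interactions(config$frag1_ibed), fm,
                     config$score_threshold, "frag1")
    c4 <- load_calls(read_interactions(config$frag4_ibed), bins,
                     config$score_threshold, "frag4")
    merge_resolutions(c1, c4, baits = baits)
  })
  log_line("interactions: %d merged calls", nrow(ix))
  stats <- stage("interactions", interactome_stats(ix))
  write_interactions(ix, p("merged_calls.ibed"))

  links <- stage("v2g", map_variants_to_genes(proxies, peaks, fm, baits, ix))
  log_line("v2g: %d links at %d loci", nrow(links),
           length(unique(links$locus)))
  write_links(links, p("links.tsv"))
  write_longrange(links, p("links.longrange.txt"))

  expr <- if (!is.null(config$expression_tsv)) {
    stage("expression", read_expression(config$expression_tsv))
  }
  sentinels <- unique(data.frame(
    id = proxies$sentinel_id,
    chrom = proxies$chrom[match(proxies$sentinel_id, proxies$proxy_id)],
    pos = proxies$pos[match(proxies$sentinel_id, proxies$proxy_id)],
    stringsAsFactors = FALSE))
  sentinels <- sentinels[!is.na(sentinels$pos), , drop = FALSE]
  summary <- if (nrow(links)) {
    stage("summary", summarize_loci(links, expression = expr, genes = genes,
                                    sentinels = sentinels))
  }
  if (!is.null(summary)) {
    utils::write.table(summary$per_locus, p("locus_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  bundle <- structure(list(fragment_map = fm, bins = bins, baits = baits,
                           interactome = ix, stats = stats, links = links,
                           summary = summary, config = config,
                           paths = list(outdir = config$outdir)),
                      class = "v2g_bundle")
  write_report(bundle, p("report.txt"))
  bundle
}

#' Write a human-readable pipeline report with a JSON twin
#'
#' @param bundle A `v2g_bundle` from [run_pipeline()].
#' @param path Path of the text report; the machine-readable twin is written
#'   next to it with extension `.json`.
#' @return `path`, invisibly.
#' @export
write_report <- function(bundle, path) {
  if (is.null(bundle) || !inherits(bundle, "v2g_bundle")) {
    stop("empty or invalid bundle", call. = FALSE)
  }
  counts <- if (!is.null(bundle$summary)) bundle$summary$counts else
    list(n_loci = 0L, n_distinct_proxies = 0L, n_distinct_genes = 0L)
  lines <- c(
    "variant-to-gene mapping report",
    sprintf("fragments: %d", nrow(bundle$fragment_map)),
    sprintf("bait fragments: %d", length(unique(bundle$baits$frag_id))),
    sprintf("interactions (merged): %d", bundle$stats$n_calls),
    sprintf("  bait-to-bait: %.1f%%; trans: %.2f%%; median cis: %s bp",
            bundle$stats$pct_bait_to_bait, bundle$stats$pct_trans,
            format(bundle$stats$median_cis_bp)),
    sprintf("loci with links: %d", counts$n_loci),
    sprintf("distinct proxies: %d", counts$n_distinct_proxies),
    sprintf("distinct genes: %d", counts$n_distinct_genes))
  if (!is.null(counts$category_fractions)) {
    cf <- counts$category_fractions
    lines <- c(lines, sprintf(
      "categories: nearest_only %.0f%%, nearest_and_distant %.0f%%, distant_only %.0f%%",
      100 * cf[["nearest_only"]], 100 * cf[["nearest_and_distant"]],
      100 * cf[["distant_only"]]))
  }
  writeLines(lines, path)
  json <- list(n_fragments = nrow(bundle$fragment_map),
               n_bait_fragments = length(unique(bundle$baits$frag_id)),
               n_interactions = bundle$stats$n_calls,
               pct_bait_to_bait = bundle$stats$pct_bait_to_bait,
               pct_trans = bundle$stats$pct_trans,
               median_cis_bp = bundle$stats$median_cis_bp,
               counts = counts[!vapply(counts, is.table, TRUE)])
  if (!is.null(counts$category_fractions)) {
    json$category_fractions <- as.list(counts$category_fractions)
  }
  jsonlite::write_json(json, sub("\\.[^.]*$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.v2g_bundle <- function(x, ...) {
  cat("v2g_bundle:\n")
  print(x$stats)
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
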