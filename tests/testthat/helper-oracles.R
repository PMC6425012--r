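# Brute-force oracles, independent of the package's implementation paths
# (plain loops and string scans; no interval-tree machinery).

# naive digestion: scan for every (possibly overlapping) site occurrence
oracle_digest <- function(seq, site = "GATC") {
  seq <- toupper(seq)
  n <- nchar(seq)
  k <- nchar(site)
  cuts <- integer(0)
  for (i in seq_len(max(0, n - k + 1))) {
    if (substr(seq, i, i + k - 1) == site) cuts <- c(cuts, i - 1L)
  }
  bounds <- unique(c(0L, cuts[cuts > 0 & cuts < n], n))
  bounds <- sort(bounds)
  data.frame(start = bounds[-length(bounds)], end = bounds[-1])
}

# O(n*m) half-open overlap
oracle_overlap <- function(regions, peaks) {
  vapply(seq_len(nrow(regions)), function(i) {
    any(peaks$chrom == regions$chrom[i] &
          pmax(peaks$start, regions$start[i]) <
            pmin(peaks$end, regions$end[i]))
  }, logical(1))
}

# exhaustive 2x2 haplotype contingency r^2
oracle_r2 <- function(x, y) {
  n <- length(x)
  n11 <- sum(x == 1 & y == 1)
  pab <- n11 / n
  pa <- sum(x) / n
  pb <- sum(y) / n
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_len = 500) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# shared default synthetic study (built once per test run)
.study_cache <- new.env(parent = emptyenv())
default_study <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- generate_study(seed = seed)
  }
  .study_cache[[key]]
}

run_study_v2g <- function(st, score_threshold = 5) {
  c1 <- suppressMessages(load_calls(st$calls_frag1, st$fragment_map,
                                    score_threshold, "frag1"))
  c4 <- suppressMessages(load_calls(st$calls_frag4, st$bins,
                                    score_threshold, "frag4"))
  ix <- merge_resolutions(c1, c4, baits = st$baits)
  links <- map_variants_to_genes(st$proxies, st$peaks, st$fragment_map,
                                 st$baits, ix)
  list(ix = ix, links = links)
}

link_key <- function(d) sort(unique(paste(d$locus, d$proxy_id, d$symbol)))

# independent re-check of the four linkage predicates with plain loops
oracle_check_link <- function(link, st, ix) {
  fm <- st$fragment_map
  pk <- st$peaks
  open_at <- function(chrom, pos) {
    any(pk$chrom == chrom & pk$start <= pos - 1 & pos - 1 < pk$end)
  }
  frag_of <- function(chrom, pos0) {
    f <- fm[fm$chrom == chrom & fm$start <= pos0 & pos0 < fm$end, ]
    f$frag_id[1]
  }
  pf <- frag_of(link$chrom, link$pos - 1)
  gene_baits <- st$baits[st$baits$gene_id == link$gene_id, , drop = FALSE]
  bait_open <- any(vapply(seq_len(nrow(gene_baits)), function(i) {
    any(pk$chrom == gene_baits$chrom[i] &
          pmax(pk$start, gene_baits$start[i]) <
            pmin(pk$end, gene_baits$end[i]))
  }, logical(1)))
  loop <- any(vapply(seq_len(nrow(ix)), function(i) {
    oe_has_proxy <- ix$oe_chr[i] == link$chrom &&
      ix$oe_start[i] <= link$pos - 1 && link$pos - 1 < ix$oe_end[i]
    bait_hits_gene <- any(ix$bait_chr[i] == gene_baits$chrom &
                            pmax(ix$bait_start[i], gene_baits$start) <
                              pmin(ix$bait_end[i], gene_baits$end))
    oe_has_proxy && bait_hits_gene
  }, logical(1)))
  c(proxy_open = open_at(link$chrom, link$pos),
    not_in_bait = !(pf %in% unique(st$baits$frag_id)),
    loop = loop,
    promoter_open = bait_open)
}
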