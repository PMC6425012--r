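# All generator randomness flows from one integer seed through named
# sub-streams, so fixtures are bit-reproducible and independent of call order.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 100000L
  (abs(as.integer(seed)) %% 20000L) * 100000L + h
}

#' Generate a random genome with controlled restriction-site density
#'
#' Background bases are i.i.d. uniform over A/C/G/T with accidental `GATC`
#' occurrences removed, then `GATC` motifs are planted as a Poisson process
#' at the requested density — so the realized fragment-size distribution is
#' controlled by `site_density` alone (expected mean fragment size
#' `1000 / site_density` bp).
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Chromosome lengths in bp (recycled to `n_chrom`; each >=
#'   1000).
#' @param site_density Expected GATC sites per kb (> 0). The default 2.31/kb
#'   gives a ~433 bp mean fragment, the regime of a DpnII digest of the human
#'   genome.
#' @param seed Integer seed.
#' @return List with `sequences` (named character vector) and
#'   `fragment_map` (the in-silico digest).
#' @export
generate_genome <- function(n_chrom = 3L, lengths = 1000000L,
                            site_density = 2.31, seed = 1L) {
  stopifnot(site_density > 0)
  lengths <- rep_len(as.integer(lengths), n_chrom)
  if (any(lengths < 1000L)) stop("chromosome length < 1 kb", call. = FALSE)
  set.seed(substream_seed(seed, "genome"))
  seqs <- character(n_chrom)
  names(seqs) <- sprintf("chr%d", seq_len(n_chrom))
  for (i in seq_len(n_chrom)) {
    len <- lengths[i]
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    # scrub accidental GATC: mutating the A to C cannot create a new site
    repeat {
      hits <- gregexpr("GATC", paste(bases, collapse = ""), fixed = TRUE)[[1]]
      if (hits[1] == -1L) break
      bases[hits + 1L] <- "C"
    }
    n_sites <- stats::rpois(1, len * site_density / 1000)
    pos <- sort(sample.int(len - 4L, min(n_sites, len %/% 8L)))
    pos <- pos[c(TRUE, diff(pos) >= 4L)]  # keep planted sites disjoint
    bases[pos] <- "G"; bases[pos + 1L] <- "A"
    bases[pos + 2L] <- "T"; bases[pos + 3L] <- "C"
    seqs[i] <- paste(bases, collapse = "")
  }
  list(sequences = seqs, fragment_map = digest_genome(seqs))
}

#' Generate random gene models on a fragment map
#'
#' Places each TSS on its own restriction fragment (uniformly within the
#' fragment); 10% of genes receive a second TSS (an alternative promoter) on
#' a different fragment. Strands are random; 85% of genes are protein-coding.
#'
#' @param fm A `fragment_map`.
#' @param n_genes Number of genes (at most a quarter of the fragment count).
#' @param seed Integer seed.
#' @return TSS table as from [read_tss()].
#' @export
generate_genes <- function(fm, n_genes, seed = 1L) {
  if (n_genes > nrow(fm) / 4) {
    stop("infeasible gene density: n_genes > fragment count / 4",
         call. = FALSE)
  }
  set.seed(substream_seed(seed, "genes"))
  n_alt <- floor(n_genes * 0.10)
  frag_idx <- sample.int(nrow(fm), n_genes + n_alt)
  tss_on <- function(i) {
    f <- fm[i, ]
    as.integer(f$start + sample.int(f$end - f$start, 1L))
  }
  gene_id <- sprintf("G%04d", seq_len(n_genes))
  symbol <- sprintf("GENE%d", seq_len(n_genes))
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  biotype <- sample(c("protein_coding", "lincRNA"), n_genes, replace = TRUE,
                    prob = c(0.85, 0.15))
  rows <- data.frame(chrom = fm$chrom[frag_idx[seq_len(n_genes)]],
                     tss = vapply(frag_idx[seq_len(n_genes)], tss_on, 1L),
                     strand = strand, gene_id = gene_id, symbol = symbol,
                     biotype = biotype, stringsAsFactors = FALSE)
  if (n_alt > 0) {
    alt_idx <- frag_idx[n_genes + seq_len(n_alt)]
    alt <- rows[seq_len(n_alt), , drop = FALSE]
    alt$chrom <- fm$chrom[alt_idx]
    alt$tss <- vapply(alt_idx, tss_on, 1L)
    rows <- rbind(rows, alt)
  }
  rownames(rows) <- NULL
  rows
}

#' Generate a haplotype panel with planted sentinel-proxy LD structure
#'
#' Background variants are independent with allele frequencies uniform in
#' (0.2, 0.5). Within each block, every proxy column is the sentinel column
#' with independent per-haplotype allele flips at `flip_rate`, so the
#' expected r2 decreases monotonically with the flip rate (r2 = 1 exactly at
#' rate 0). Blocks that come out monomorphic are re-drawn (with a message).
#'
#' @param variants `data.frame` `id`, `chrom`, `pos` of all panel variants.
#' @param blocks List of blocks, each a list with `sentinel` (id), `proxies`
#'   (ids) and `flip_rate` in `[0, 0.5)`.
#' @param n_hap Number of haplotypes (>= 2).
#' @param seed Integer seed.
#' @return List with `panel` (a `haplotype_panel`) and `realized_r2`
#'   (`data.frame` `sentinel_id`, `proxy_id`, `flip_rate`, `r2`).
#' @export
generate_haplotypes <- function(variants, blocks, n_hap = 1000L, seed = 1L) {
  for (b in blocks) {
    stopifnot(b$flip_rate >= 0, b$flip_rate < 0.5)
  }
  set.seed(substream_seed(seed, "haplotypes"))
  n_var <- nrow(variants)
  mat <- vapply(seq_len(n_var), function(j) {
    stats::rbinom(n_hap, 1L, stats::runif(1, 0.2, 0.5))
  }, integer(n_hap))
  colnames(mat) <- variants$id
  for (b in blocks) {
    s <- mat[, b$sentinel]
    attempt <- 0L
    while (length(unique(s)) < 2) {
      attempt <- attempt + 1L
      message("monomorphic sentinel column; re-drawing (attempt ", attempt, ")")
      s <- stats::rbinom(n_hap, 1L, 0.4)
    }
    mat[, b$sentinel] <- s
    for (p in b$proxies) {
      repeat {
        flips <- stats::rbinom(n_hap, 1L, b$flip_rate)
        col <- as.integer(xor(s, flips))
        if (length(unique(col)) >= 2) break
        message("monomorphic proxy column for ", p, "; re-drawing")
      }
      mat[, p] <- col
    }
  }
  panel <- haplotype_panel(variants, mat)
  rows <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(sentinel_id = b$sentinel, proxy_id = b$proxies,
               flip_rate = b$flip_rate,
               r2 = vapply(b$proxies,
                           function(p) compute_r2(panel, b$sentinel, p),
                           numeric(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  list(panel = panel, realized_r2 = rows)
}

#' Default synthetic-study configuration
#'
#' The defaults define the standard validation conditions: a 3 x 1 Mb
#' genome at DpnII-like site density, 80 genes, 20 planted variant-to-gene
#' loci, the score-5 significance cutoff, all decoy classes enabled, and
#' background interaction noise with ~14% bait-to-bait and ~1% trans calls.
#'
#' @param n_chrom,chrom_length,site_density Genome shape (see
#'   [generate_genome()]).
#' @param n_genes Genes to annotate.
#' @param n_loci Planted variant-to-gene loci.
#' @param frag4_frac Fraction of planted loci detectable only at 4-fragment
#'   resolution (longer-range loops).
#' @param score_threshold Significance cutoff planted loops exceed and decoy
#'   loops fall below.
#' @param decoys Enable the four decoy classes (each violating exactly one
#'   linkage predicate)?
#' @param n_decoys_per_class Decoy loci per class when enabled.
#' @param n_noise_calls Background significant calls (bait-to-bait, trans and
#'   plain cis noise).
#' @param frac_bait_to_bait,frac_trans Composition of the background calls.
#' @param n_noise_peaks Open-chromatin peaks on fragments unrelated to any
#'   locus.
#' @param n_noise_subthreshold Sub-threshold rows included in the raw call
#'   tables (dropped on load).
#' @return Named list of class `study_config`.
#' @export
study_config <- function(n_chrom = 3L, chrom_length = 1000000L,
                         site_density = 2.31, n_genes = 80L, n_loci = 20L,
                         frag4_frac = 0.3, score_threshold = 5,
                         decoys = TRUE, n_decoys_per_class = 3L,
                         n_noise_calls = 150L, frac_bait_to_bait = 0.14,
                         frac_trans = 0.01, n_noise_peaks = 40L,
                         n_noise_subthreshold = 30L) {
  structure(as.list(environment()), class = "study_config")
}

new_ibed_row <- function(b, o, reads, score) {
  data.frame(bait_chr = b$chrom, bait_start = b$start, bait_end = b$end,
             bait_name = b$name, oe_chr = o$chrom, oe_start = o$start,
             oe_end = o$end, oe_name = o$name, N_reads = reads,
             score = score, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Builds a genome, gene annotation, promoter bait design, ATAC-seq-like
#' peaks, interaction calls at 1- and 4-fragment resolution, a proxy table
#' and an expression table, such that the variant-to-gene pipeline has an
#' exactly known expected output. For each planted locus a causal proxy (or
#' two) is placed in a non-bait fragment, covered by a peak, and looped
#' (score above threshold) to the open promoter of one or two target genes.
#' Decoy loci each violate exactly one of the four linkage predicates (closed
#' proxy, proxy inside a bait, sub-threshold loop, closed target promoter) so
#' failures can be attributed to a rule. Background noise includes
#' bait-to-bait calls, rare trans calls, plain cis noise and sub-threshold
#' rows.
#'
#' Every allocation (target baits, causal fragments, decoy fragments, noise
#' anchors) uses a distinct 4-fragment bin, so that bin-resolution anchors
#' can never accidentally connect two planted elements.
#'
#' @param config A [study_config()].
#' @param seed Integer seed; the same seed reproduces the study exactly.
#' @return List of class `synthetic_study` with elements `sequences`,
#'   `fragment_map`, `bins`, `genes`, `baits`, `peaks`, `calls_frag1`,
#'   `calls_frag4` (raw ibed tables incl. sub-threshold rows), `proxies`
#'   (with positions), `sentinels`, `expression`, `truth` (expected link
#'   table), `truth_summary` (expected per-locus table), `config`, `seed`.
#' @export
generate_study <- function(config = study_config(), seed = 1L) {
  g <- generate_genome(config$n_chrom, config$chrom_length,
                       config$site_density, seed = seed)
  fm <- g$fragment_map
  bins <- bin_fragments(fm, 4L)
  genes <- generate_genes(fm, config$n_genes, seed = seed)
  baits <- design_baits(fm, genes)
  set.seed(substream_seed(seed, "study"))

  frag_bin <- integer(nrow(fm))  # bin id per frag_id
  for (i in seq_len(nrow(bins))) {
    frag_bin[bins$first_frag[i]:bins$last_frag[i]] <- bins$bin_id[i]
  }
  bait_frag_ids <- unique(baits$frag_id)
  used_bins <- unique(frag_bin[bait_frag_ids])  # no allocation next to a bait
  claim_bin <- function(bin_id) used_bins <<- c(used_bins, bin_id)

  frag_iv <- function(fid) {
    f <- fm[fid, ]
    list(chrom = f$chrom, start = f$start, end = f$end,
         name = sprintf("frag%d", fid), mid = (f$start + f$end) / 2)
  }
  bin_iv <- function(fid) {
    b <- bins[frag_bin[fid], ]
    list(chrom = b$chrom, start = b$start, end = b$end,
         name = sprintf("bin%d", b$bin_id), mid = (b$start + b$end) / 2)
  }
  # a non-bait fragment in an unclaimed bin, optionally near an anchor
  pick_free_frag <- function(chrom = NULL, near_mid = NULL,
                             dist_range = c(20000, 300000)) {
    cand <- which(!(fm$frag_id %in% bait_frag_ids) &
                    !(frag_bin %in% used_bins))
    if (!is.null(chrom)) cand <- cand[fm$chrom[cand] == chrom]
    if (!is.null(near_mid)) {
      mid <- (fm$start[cand] + fm$end[cand]) / 2
      d <- abs(mid - near_mid)
      sel <- cand[d >= dist_range[1] & d <= dist_range[2]]
      if (!length(sel)) sel <- cand[d <= 500000]
      cand <- sel
    }
    if (!length(cand)) stop("conflicting placements: no free fragment left",
                            call. = FALSE)
    fid <- fm$frag_id[cand[sample.int(length(cand), 1L)]]
    claim_bin(frag_bin[fid])
    fid
  }

  # -- choose target genes: single-TSS genes on an exclusive bait fragment
  # (no other gene's TSS on it), with all target baits in distinct bins, so
  # a planted loop can implicate exactly one open promoter.
  tss_count <- table(genes$gene_id)
  singles <- names(tss_count)[tss_count == 1]
  gene_bait <- vapply(split(baits$frag_id, baits$gene_id), min, 1L)
  gene_rows <- unique(baits[, c("frag_id", "gene_id")])
  genes_per_frag <- table(gene_rows$frag_id)
  exclusive <- singles[genes_per_frag[as.character(gene_bait[singles])] == 1]
  pool <- sample(exclusive)
  target_genes <- character(0)
  target_bins <- integer(0)
  for (gn in pool) {
    b <- frag_bin[gene_bait[[gn]]]
    if (b %in% target_bins) next
    target_genes <- c(target_genes, gn)
    target_bins <- c(target_bins, b)
    if (length(target_genes) >= config$n_loci + config$n_loci %/% 3 + 8) break
  }
  if (length(target_genes) < config$n_loci) {
    stop("conflicting placements: not enough isolated target genes",
         call. = FALSE)
  }

  peaks <- list()
  add_peak <- function(fid) {
    f <- fm[fid, ]
    peaks[[length(peaks) + 1L]] <<- data.frame(
      chrom = f$chrom, start = f$start, end = f$end, stringsAsFactors = FALSE)
  }
  calls1 <- list()
  calls4 <- list()
  proxy_rows <- list()
  truth_rows <- list()
  next_gene <- 1L
  take_gene <- function() {
    gn <- target_genes[next_gene]
    next_gene <<- next_gene + 1L
    gn
  }
  sym_of <- function(gn) genes$symbol[match(gn, genes$gene_id)][1]
  plant_loop <- function(bait_fid, oe_fid, frag4_only) {
    score <- stats::runif(1, 5.5, 11.5)
    reads <- stats::rpois(1, 50) + 1L
    if (!frag4_only) {
      calls1[[length(calls1) + 1L]] <<-
        new_ibed_row(frag_iv(bait_fid), frag_iv(oe_fid), reads, score)
    }
    calls4[[length(calls4) + 1L]] <<-
      new_ibed_row(bin_iv(bait_fid), bin_iv(oe_fid), reads,
                   stats::runif(1, 5.5, 11.5))
  }

  n_frag4 <- round(config$n_loci * config$frag4_frac)
  for (li in seq_len(config$n_loci)) {
    locus <- sprintf("L%02d", li)
    frag4_only <- li <= n_frag4
    gene1 <- take_gene()
    locus_genes <- gene1
    bait1 <- gene_bait[[gene1]]
    if (stats::runif(1) < 0.3 && next_gene <= length(target_genes)) {
      # second target on the same chromosome, close enough to loop
      for (j in next_gene:length(target_genes)) {
        cand <- target_genes[j]
        cb <- gene_bait[[cand]]
        if (fm$chrom[cb] == fm$chrom[bait1] &&
            abs((fm$start[cb] + fm$end[cb]) / 2 -
                  (fm$start[bait1] + fm$end[bait1]) / 2) < 400000) {
          target_genes[j] <- target_genes[next_gene]
          target_genes[next_gene] <- cand
          locus_genes <- c(locus_genes, take_gene())
          break
        }
      }
    }
    causal <- pick_free_frag(chrom = fm$chrom[bait1],
                             near_mid = (fm$start[bait1] + fm$end[bait1]) / 2)
    add_peak(causal)
    n_prox <- sample(1:2, 1L)
    f <- fm[causal, ]
    pos <- f$start + sample.int(f$end - f$start, n_prox)
    sent <- sprintf("rsS%02d", li)
    ids <- c(sent, if (n_prox > 1) sprintf("rsP%02d_%d", li,
                                           seq_len(n_prox - 1L)))
    r2 <- c(1, if (n_prox > 1) round(stats::runif(n_prox - 1L, 0.85, 1), 2))
    gset <- sample(c("DEXA", "Heel", "Both"), 1L)
    proxy_rows[[length(proxy_rows) + 1L]] <- data.frame(
      locus = locus, sentinel_id = sent, proxy_id = ids, r2 = r2,
      chrom = f$chrom, pos = as.integer(sort(pos)), population = "EUR",
      gwas_set = gset, stringsAsFactors = FALSE)
    for (gn in locus_genes) {
      add_peak(gene_bait[[gn]])
      plant_loop(gene_bait[[gn]], causal, frag4_only)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        locus = locus, sentinel_id = sent, proxy_id = ids, r2 = r2,
        gene_id = gn, symbol = sym_of(gn), gwas_set = gset,
        stringsAsFactors = FALSE)
    }
  }
  target_used <- target_genes[seq_len(next_gene - 1L)]

  # -- decoys: each violates exactly one linkage predicate --------------------
  if (isTRUE(config$decoys)) {
    open_targets <- sample(target_used)
    decoy_proxy <- function(kind, di) {
      anchor_gene <- open_targets[1 + (di %% length(open_targets))]
      bait_fid <- gene_bait[[anchor_gene]]
      sent <- sprintf("rsD%s%02d", kind, di)
      list(gene = anchor_gene, bait_fid = bait_fid, sent = sent)
    }
    add_decoy_row <- function(sent, chrom, pos) {
      proxy_rows[[length(proxy_rows) + 1L]] <<- data.frame(
        locus = paste0("decoy_", sent), sentinel_id = sent, proxy_id = sent,
        r2 = 1, chrom = chrom, pos = as.integer(pos), population = "EUR",
        gwas_set = "Heel", stringsAsFactors = FALSE)
    }
    for (di in seq_len(config$n_decoys_per_class)) {
      # (a) closed proxy: no peak over its fragment
      d <- decoy_proxy("a", di)
      fid <- pick_free_frag(chrom = fm$chrom[d$bait_fid],
                            near_mid = (fm$start[d$bait_fid] +
                                          fm$end[d$bait_fid]) / 2)
      add_decoy_row(d$sent, fm$chrom[fid],
                    fm$start[fid] + sample.int(fm$end[fid] - fm$start[fid], 1))
      plant_loop(d$bait_fid, fid, frag4_only = FALSE)

      # (b) proxy inside a baited promoter fragment (open, looping)
      host <- open_targets[1 + ((di + 1) %% length(open_targets))]
      host_fid <- gene_bait[[host]]
      anchors <- setdiff(open_targets[fm$chrom[gene_bait[open_targets]] ==
                                        fm$chrom[host_fid]], host)
      anchor_fid <- if (length(anchors)) gene_bait[[anchors[1]]]
                    else gene_bait[[setdiff(open_targets, host)[1]]]
      add_decoy_row(sprintf("rsDb%02d", di), fm$chrom[host_fid],
                    fm$start[host_fid] +
                      sample.int(fm$end[host_fid] - fm$start[host_fid], 1))
      # significant loop to an open promoter, so only the in-bait rule blocks it
      calls1[[length(calls1) + 1L]] <- new_ibed_row(
        frag_iv(anchor_fid), frag_iv(host_fid), stats::rpois(1, 50) + 1L,
        stats::runif(1, 5.5, 11.5))

      # (c) open non-bait proxy whose only loop is sub-threshold
      d <- decoy_proxy("c", di)
      fid <- pick_free_frag(chrom = fm$chrom[d$bait_fid],
                            near_mid = (fm$start[d$bait_fid] +
                                          fm$end[d$bait_fid]) / 2)
      add_peak(fid)
      add_decoy_row(d$sent, fm$chrom[fid],
                    fm$start[fid] + sample.int(fm$end[fid] - fm$start[fid], 1))
      calls1[[length(calls1) + 1L]] <- new_ibed_row(
        frag_iv(d$bait_fid), frag_iv(fid), stats::rpois(1, 10) + 1L,
        stats::runif(1, 1, 4.5))

      # (d) open non-bait proxy looping to a closed promoter
      closed_gene <- setdiff(singles, target_used)
      closed_gene <- closed_gene[!(frag_bin[gene_bait[closed_gene]] %in%
                                     target_bins)][di]
      cb <- gene_bait[[closed_gene]]
      sent <- sprintf("rsDd%02d", di)
      fid <- pick_free_frag(chrom = fm$chrom[cb],
                            near_mid = (fm$start[cb] + fm$end[cb]) / 2)
      add_peak(fid)
      add_decoy_row(sent, fm$chrom[fid],
                    fm$start[fid] + sample.int(fm$end[fid] - fm$start[fid], 1))
      calls1[[length(calls1) + 1L]] <- new_ibed_row(
        frag_iv(cb), frag_iv(fid), stats::rpois(1, 50) + 1L,
        stats::runif(1, 5.5, 11.5))
    }
  }

  # -- background noise -------------------------------------------------------
  nontarget <- setdiff(unique(genes$gene_id), target_used)
  n_b2b <- round(config$n_noise_calls * config$frac_bait_to_bait)
  n_trans <- if (config$n_noise_calls > 0) {
    max(1L, round(config$n_noise_calls * config$frac_trans))
  } else 0L
  n_cis <- max(0L, config$n_noise_calls - n_b2b - n_trans)
  rand_gene_bait <- function() gene_bait[[sample(nontarget, 1L)]]
  nt_baits <- unname(gene_bait[nontarget])
  for (i in seq_len(n_b2b)) {
    b1 <- rand_gene_bait()
    same <- nt_baits[fm$chrom[nt_baits] == fm$chrom[b1] & nt_baits != b1]
    if (!length(same)) next
    b2 <- same[sample.int(length(same), 1L)]
    calls1[[length(calls1) + 1L]] <- new_ibed_row(
      frag_iv(b1), frag_iv(b2), stats::rpois(1, 30) + 1L,
      stats::runif(1, 5, 10))
  }
  if (length(unique(fm$chrom)) < 2) n_trans <- 0L
  for (i in seq_len(n_trans)) {
    b <- rand_gene_bait()
    other <- setdiff(unique(fm$chrom), fm$chrom[b])
    fid <- pick_free_frag(chrom = other[sample.int(length(other), 1L)])
    calls1[[length(calls1) + 1L]] <- new_ibed_row(
      frag_iv(b), frag_iv(fid), stats::rpois(1, 20) + 1L,
      stats::runif(1, 5, 8))
  }
  for (i in seq_len(n_cis)) {
    b <- rand_gene_bait()
    fid <- tryCatch(pick_free_frag(chrom = fm$chrom[b],
                                   near_mid = (fm$start[b] + fm$end[b]) / 2,
                                   dist_range = c(5000, 400000)),
                    error = function(e) NA_integer_)
    if (is.na(fid)) break
    row <- new_ibed_row(frag_iv(b), frag_iv(fid), stats::rpois(1, 25) + 1L,
                        stats::runif(1, 5, 9))
    if (i %% 3 == 0) {
      calls4[[length(calls4) + 1L]] <- new_ibed_row(
        bin_iv(b), bin_iv(fid), row$N_reads, row$score)
    } else {
      calls1[[length(calls1) + 1L]] <- row
    }
  }
  for (i in seq_len(config$n_noise_peaks)) {
    fid <- tryCatch(pick_free_frag(), error = function(e) NA_integer_)
    if (is.na(fid)) break
    add_peak(fid)
  }
  for (i in seq_len(config$n_noise_subthreshold)) {
    b <- rand_gene_bait()
    fid <- tryCatch(pick_free_frag(chrom = fm$chrom[b],
                                   near_mid = (fm$start[b] + fm$end[b]) / 2,
                                   dist_range = c(5000, 400000)),
                    error = function(e) NA_integer_)
    if (is.na(fid)) break
    calls1[[length(calls1) + 1L]] <- new_ibed_row(
      frag_iv(b), frag_iv(fid), stats::rpois(1, 5) + 1L, stats::runif(1, 0, 4.9))
  }

  proxies <- do.call(rbind, proxy_rows)
  truth <- do.call(rbind, truth_rows)
  peaks <- unique(do.call(rbind, peaks))
  peaks <- peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
  rownames(peaks) <- NULL
  expression <- data.frame(
    gene_id = unique(genes$gene_id),
    symbol = genes$symbol[match(unique(genes$gene_id), genes$gene_id)],
    fpkm = round(stats::rlnorm(length(unique(genes$gene_id)), log(5), 1.2), 2),
    stringsAsFactors = FALSE)
  sentinels <- unique(proxies[proxies$proxy_id == proxies$sentinel_id,
                              c("sentinel_id", "chrom", "pos")])
  names(sentinels)[1] <- "id"
  truth_summary <- summarize_loci(truth)

  structure(list(sequences = g$sequences, fragment_map = fm, bins = bins,
                 genes = genes, baits = baits, peaks = peaks,
                 calls_frag1 = do.call(rbind, calls1),
                 calls_frag4 = do.call(rbind, calls4),
                 proxies = proxies, sentinels = sentinels,
                 expression = expression, truth = truth,
                 truth_summary = truth_summary, config = config, seed = seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study (seed %d): %d chrom, %d fragments, %d genes, %d planted loci\n",
              x$seed, length(x$sequences), nrow(x$fragment_map),
              length(unique(x$genes$gene_id)),
              length(unique(x$truth$locus))))
  invisible(x)
}

#' Write a synthetic study to disk in standard formats
#'
#' Emits genome FASTA, TSS TSV, peaks BED, ibed call tables at both
#' resolutions, proxy CSV (with positions), expression TSV and the planted
#' truth as JSON.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(study$sequences),
                              p("genome.fa"))
  write_tss(study$genes, p("tss.tsv"))
  write_intervals(study$peaks, p("peaks.bed"))
  write_interactions(study$calls_frag1, p("calls_frag1.ibed"))
  write_interactions(study$calls_frag4, p("calls_frag4.ibed"))
  utils::write.csv(study$proxies, p("proxies.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.table(study$expression, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(study$truth, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  out <- c(genome = p("genome.fa"), tss = p("tss.tsv"), peaks = p("peaks.bed"),
           frag1 = p("calls_frag1.ibed"), frag4 = p("calls_frag4.ibed"),
           proxies = p("proxies.csv"), expression = p("expression.tsv"),
           truth = p("truth.json"))
  invisible(out)
}
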