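test_that("proxies inside baited promoter fragments are excluded regardless of loops", {
  fm <- digest_genome(c(chr1 = paste(rep("GATCAA", 60), collapse = "")))
  genes <- data.frame(chrom = "chr1", tss = c(3L, 123L), strand = "+",
                      gene_id = c("G1", "G2"), symbol = c("A", "B"),
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  baits <- design_baits(fm, genes)
  # peaks over both baits and over a free fragment (frag 31: 180-186)
  peaks <- data.frame(chrom = "chr1", start = c(0L, 120L, 180L),
                      end = c(6L, 126L, 186L))
  calls <- data.frame(bait_chr = "chr1", bait_start = c(120L, 120L),
                      bait_end = c(126L, 126L), bait_name = "b",
                      oe_chr = "chr1", oe_start = c(180L, 0L),
                      oe_end = c(186L, 6L), oe_name = "o", N_reads = 10L,
                      score = 7, stringsAsFactors = FALSE)
  c1 <- suppressMessages(load_calls(calls, fm, 5, "frag1"))
  ix <- merge_resolutions(c1, c1[0, ])
  proxies <- data.frame(sentinel_id = c("rs1", "rs2"),
                        proxy_id = c("rs1", "rs2"), r2 = 1, chrom = "chr1",
                        pos = c(183L, 3L), stringsAsFactors = FALSE)
  links <- map_variants_to_genes(proxies, peaks, fm, baits, ix)
  # rs2 sits in G1's baited fragment and has a significant loop to open B: excluded
  expect_identical(unique(links$proxy_id), "rs1")
  expect_identical(unique(links$symbol), "B")

  # proxy on a chromosome absent from the map -> fragment-map mismatch
  off <- transform(proxies, chrom = "chrZ")
  expect_error(map_variants_to_genes(off, peaks, fm, baits, ix),
               "fragment-map mismatch")
})

test_that("planted synthetic truth is recovered exactly with all decoys enabled", {
  st <- default_study()
  res <- run_study_v2g(st)
  expect_identical(link_key(res$links), link_key(st$truth))
  # no decoy locus leaks through
  expect_false(any(grepl("^decoy", res$links$locus)))
})

test_that("every emitted link passes an independent re-check of the four predicates", {
  st <- default_study()
  res <- run_study_v2g(st)
  idx <- seq_len(nrow(res$links))
  if (length(idx) > 12) idx <- sort(sample(idx, 12))
  for (i in idx) {
    checks <- oracle_check_link(res$links[i, ], st, res$ix)
    expect_true(all(checks), label = paste("link", i, "predicates"))
  }
})

test_that("raising the r2 threshold never adds links", {
  st <- default_study()
  res <- run_study_v2g(st)
  pr <- st$proxies
  for (thr in c(0.4, 0.8, 0.9, 1.0)) {
    sub <- pr[pr$r2 >= thr, , drop = FALSE]
    l <- map_variants_to_genes(sub, st$peaks, st$fragment_map, st$baits,
                               res$ix)
    if (thr > 0.4) {
      expect_true(all(link_key(l) %in% prev))
    }
    prev <- link_key(l)
  }
})

test_that("locus classification distinguishes nearest, mixed, and distant-only gene sets", {
  genes <- data.frame(
    chrom = "chr7",
    tss = c(1000L, 5000L, 9000L, 20000L),
    strand = "+",
    gene_id = c("NEAR", "MID", "FAR", "VERYFAR"),
    symbol = c("NEAR", "MID", "FAR", "VERYFAR"),
    biotype = "protein_coding", stringsAsFactors = FALSE)
  expect_equal(classify_locus("NEAR", genes, "chr7", 1100L)$category,
               "nearest_only")
  expect_equal(classify_locus(c("NEAR", "FAR"), genes, "chr7", 1100L)$category,
               "nearest_and_distant")
  expect_equal(classify_locus(c("MID", "FAR"), genes, "chr7", 1100L)$category,
               "distant_only")
  expect_error(classify_locus(character(0), genes, "chr7", 1100L), "empty")
  # ties broken by smaller gene_id, with a message
  tied <- rbind(genes, data.frame(chrom = "chr7", tss = 1200L, strand = "+",
                                  gene_id = "AAA", symbol = "AAA",
                                  biotype = "protein_coding"))
  expect_message(r <- classify_locus("AAA", tied, "chr7", 1100L), "tie")
  expect_equal(r$nearest, "AAA")
})

test_that("locus summaries count distinct entities and match brute-force set sizes", {
  one <- data.frame(locus = "L1", sentinel_id = "rs1", proxy_id = "rs1",
                    r2 = 1, symbol = "A", stringsAsFactors = FALSE)
  s1 <- summarize_loci(one)
  expect_equal(s1$counts$n_loci, 1L)
  expect_equal(s1$counts$n_distinct_proxies, 1L)
  expect_equal(s1$counts$n_distinct_genes, 1L)

  st <- default_study()
  res <- run_study_v2g(st)
  sm <- summarize_loci(res$links, genes = st$genes, sentinels = st$sentinels)
  expect_equal(sm$counts$n_loci, length(unique(res$links$locus)))
  expect_equal(sm$counts$n_distinct_proxies,
               length(unique(res$links$proxy_id)))
  expect_equal(sm$counts$n_distinct_genes, length(unique(res$links$symbol)))
  expect_equal(sm$counts$n_distinct_open_regions,
               length(unique(res$links$proxy_frag)))
  expect_true(all(sm$per_locus$category %in%
                    c("nearest_only", "nearest_and_distant", "distant_only")))
  expect_equal(sum(sm$counts$category_fractions), 1)
  expect_error(summarize_loci(one[0, ]), "no links")
})

test_that("expression percentiles follow the mean-rank convention", {
  expr <- data.frame(gene_id = sprintf("G%d", 1:4),
                     symbol = sprintf("S%d", 1:4), fpkm = c(1, 2, 3, 4))
  ann <- annotate_expression(sprintf("G%d", 1:4), expr)
  expect_equal(ann$percentile, c(25, 50, 75, 100))
  expect_equal(ann$high, c(FALSE, FALSE, TRUE, TRUE))

  # ties share the mean rank
  expr2 <- data.frame(gene_id = sprintf("G%d", 1:4), symbol = NA,
                      fpkm = c(1, 2, 2, 4))
  ann2 <- annotate_expression(c("G2", "G3"), expr2)
  expect_equal(ann2$percentile, c(62.5, 62.5))

  # missing genes: NA fpkm, undefined flag; symbol fallback works
  ann3 <- annotate_expression(c("S1", "NOPE"), expr)
  expect_equal(ann3$fpkm, c(1, NA))
  expect_true(is.na(ann3$high[2]))
})

test_that("cell-type comparison labels pair-set relations", {
  a <- data.frame(locus = c("L1", "L1", "L2", "L3", "L4"),
                  proxy_id = c("p1", "p1", "p2", "p3", "p4"),
                  symbol = c("A", "B", "C", "D", "E"),
                  stringsAsFactors = FALSE)
  b <- data.frame(locus = c("L1", "L2", "L3", "L5"),
                  proxy_id = c("p1", "p2", "px", "p5"),
                  symbol = c("A", "C", "Z", "F"),
                  stringsAsFactors = FALSE)
  cmp <- compare_celltypes(a, b)
  lab <- setNames(cmp$label, cmp$locus)
  expect_equal(lab[["L1"]], "target_subset")       # B pairs strict subset of A
  expect_equal(lab[["L2"]], "identical")
  expect_equal(lab[["L3"]], "different_target")
  expect_equal(lab[["L4"]], "absent_in_B")
  expect_equal(lab[["L5"]], "absent_in_A")

  # same target through a different proxy
  a2 <- data.frame(locus = "LX", proxy_id = "p1", symbol = "T1")
  b2 <- data.frame(locus = "LX", proxy_id = c("p9", "p9"),
                   symbol = c("T1", "T9"))
  expect_equal(compare_celltypes(a2, b2)$label, "different_proxy_same_target")

  # identical sets -> all identical (brute-force set algebra agrees)
  set.seed(16)
  rnd <- data.frame(locus = sample(c("A", "B"), 30, TRUE),
                    proxy_id = sample(sprintf("p%d", 1:5), 30, TRUE),
                    symbol = sample(sprintf("g%d", 1:5), 30, TRUE),
                    stringsAsFactors = FALSE)
  expect_true(all(compare_celltypes(rnd, rnd)$label == "identical"))
})
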