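test_that("generated genomes hit the requested restriction-site density", {
  g <- generate_genome(n_chrom = 1, lengths = 1000000L, site_density = 2.5,
                       seed = 7)
  sizes <- g$fragment_map$end - g$fragment_map$start
  expect_gte(mean(sizes), 340)
  expect_lte(mean(sizes), 460)
  # within 15% of 1000/density for a >= 100 kb chromosome
  expect_lt(abs(mean(sizes) - 400) / 400, 0.15)

  g2 <- generate_genome(n_chrom = 1, lengths = 1000000L, site_density = 2.5,
                        seed = 7)
  expect_identical(g$sequences, g2$sequences)
  expect_error(generate_genome(lengths = 500L), "1 kb")
})

test_that("generated TSSs each lie inside exactly one fragment", {
  g <- generate_genome(n_chrom = 2, lengths = 200000L, seed = 3)
  fm <- g$fragment_map
  genes <- generate_genes(fm, 40, seed = 3)
  expect_identical(genes, generate_genes(fm, 40, seed = 3))
  fid <- locate_fragment(fm, genes$chrom, genes$tss - 1L)
  expect_false(any(duplicated(fid)))  # distinct fragments per TSS
  # ~10% of genes carry an alternative promoter
  expect_equal(sum(table(genes$gene_id) == 2), 4L)
  expect_error(generate_genes(fm, nrow(fm)), "infeasible")
})

test_that("planted haplotype blocks have the prescribed LD structure", {
  variants <- data.frame(id = c("s", "p0", "p5", "n"), chrom = "chr1",
                         pos = c(100L, 200L, 300L, 400L),
                         stringsAsFactors = FALSE)
  hp <- generate_haplotypes(
    variants,
    blocks = list(list(sentinel = "s", proxies = "p0", flip_rate = 0),
                  list(sentinel = "s", proxies = "p5", flip_rate = 0.49)),
    n_hap = 5000, seed = 5)
  r2 <- setNames(hp$realized_r2$r2, hp$realized_r2$proxy_id)
  expect_equal(unname(r2["p0"]), 1)         # flip 0 -> exact copy
  expect_lt(unname(r2["p5"]), 0.05)         # flip ~0.5 -> r2 near 0
  # realized table is internally consistent with compute_r2 on the panel
  for (i in seq_len(nrow(hp$realized_r2))) {
    expect_equal(hp$realized_r2$r2[i],
                 compute_r2(hp$panel, hp$realized_r2$sentinel_id[i],
                            hp$realized_r2$proxy_id[i]))
  }
  expect_error(generate_haplotypes(
    variants, list(list(sentinel = "s", proxies = "p0", flip_rate = 0.6)),
    100, 1))
})

test_that("study generation is reproducible and its decoys each break one rule", {
  st <- default_study()
  st2 <- generate_study(seed = st$seed)
  expect_identical(st$sequences, st2$sequences)
  expect_identical(st$calls_frag1, st2$calls_frag1)
  expect_identical(st$proxies, st2$proxies)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(st, d1)
  write_study(st2, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("fixture file", f))
  }

  # decoys: exactly one of the four predicates violated
  res <- run_study_v2g(st)
  decoys <- st$proxies[grepl("^decoy", st$proxies$locus), ]
  expect_gt(nrow(decoys), 0)
  for (i in seq_len(nrow(decoys))) {
    d <- decoys[i, ]
    # evaluate the proxy-side predicates directly
    open <- variant_openness(
      data.frame(id = d$proxy_id, chrom = d$chrom, pos = d$pos),
      st$peaks)$open
    pf <- locate_fragment(st$fragment_map, d$chrom, d$pos - 1L)
    in_bait <- pf %in% unique(st$baits$frag_id)
    # loop + open-promoter side: does any retained call join this proxy to an
    # open promoter?
    oe_hit <- res$ix$oe_chr == d$chrom & res$ix$oe_start <= d$pos - 1 &
      d$pos - 1 < res$ix$oe_end
    prom <- promoter_openness(st$baits, st$peaks)
    open_gene_frags <- unique(
      st$baits$frag_id[st$baits$gene_id %in%
                         prom$genes$gene_id[prom$genes$open %in% TRUE]])
    loop_to_open <- any(vapply(which(oe_hit), function(ci) {
      any(st$fragment_map$chrom[open_gene_frags] == res$ix$bait_chr[ci] &
            pmax(st$fragment_map$start[open_gene_frags],
                 res$ix$bait_start[ci]) <
              pmin(st$fragment_map$end[open_gene_frags],
                   res$ix$bait_end[ci]))
    }, logical(1)))
    kind <- sub("^rsD([a-d]).*$", "\\1", d$sentinel_id)
    violated <- c(a = !open, b = in_bait, c = !loop_to_open,
                  d = !loop_to_open)
    expect_true(violated[[kind]], label = paste("decoy", d$sentinel_id))
    if (kind == "a") expect_true(!in_bait)
    if (kind == "b") expect_true(open)
    if (kind %in% c("c", "d")) expect_true(open && !in_bait)
    # class c has no retained loop at all; class d loops to a closed promoter
    if (kind == "c") expect_false(any(oe_hit))
    if (kind == "d") expect_true(any(oe_hit))
  }
})

test_that("a noise-free study is recovered as exactly as the noisy default", {
  cfg <- study_config(n_loci = 8L, decoys = FALSE, n_noise_calls = 0L,
                      n_noise_peaks = 0L, n_noise_subthreshold = 0L,
                      n_chrom = 2L, chrom_length = 400000L, n_genes = 40L)
  st <- generate_study(cfg, seed = 33)
  res <- run_study_v2g(st)
  expect_identical(link_key(res$links), link_key(st$truth))
  # derived PIRs equal the planted other-end set (loops only above threshold)
  ps <- derive_pirs(res$ix, baits = st$baits)
  causal_frags <- unique(locate_fragment(st$fragment_map, st$proxies$chrom,
                                         st$proxies$pos - 1L))
  causal_key <- sprintf("%s:%d-%d", st$fragment_map$chrom[causal_frags],
                        st$fragment_map$start[causal_frags],
                        st$fragment_map$end[causal_frags])
  pir_key <- sprintf("%s:%d-%d", ps$pirs$chrom, ps$pirs$start, ps$pirs$end)
  for (k in causal_key) {
    expect_true(any(vapply(seq_len(nrow(ps$pirs)), function(i) {
      p <- ps$pirs[i, ]
      parts <- strsplit(k, "[:-]")[[1]]
      p$chrom == parts[1] && p$start <= as.integer(parts[2]) &&
        as.integer(parts[3]) <= p$end
    }, logical(1))), label = paste("planted oe", k))
  }
})

test_that("the truth table is realizable: expected summary matches its own links", {
  st <- default_study()
  expect_equal(st$truth_summary$counts$n_loci,
               length(unique(st$truth$locus)))
  expect_equal(st$truth_summary$counts$n_distinct_genes,
               length(unique(st$truth$symbol)))
})
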