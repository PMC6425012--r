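# helpers: a uniform 6-bp fragment map and hand-built calls
mk_fm <- function(n_frag = 40, chroms = "chr1") {
  seqs <- setNames(rep(paste(rep("GATCAA", n_frag), collapse = ""),
                       length(chroms)), chroms)
  digest_genome(seqs)
}

mk_call <- function(map, bait_id, oe_id, score = 6, res = "frag1",
                    reads = 10L) {
  idc <- if (inherits(map, "bin_map")) "bin_id" else "frag_id"
  b <- map[map[[idc]] == bait_id, ]
  o <- map[map[[idc]] == oe_id, ]
  data.frame(bait_chr = b$chrom, bait_start = b$start, bait_end = b$end,
             bait_name = "b", oe_chr = o$chrom, oe_start = o$start,
             oe_end = o$end, oe_name = "o", N_reads = reads, score = score,
             bait_id = bait_id, oe_id = oe_id, resolution = res,
             stringsAsFactors = FALSE)
}

test_that("call loading applies an inclusive score threshold and resolves anchors", {
  fm <- mk_fm()
  rows <- rbind(mk_call(fm, 2, 10, score = 4.99)[, 1:10],
                mk_call(fm, 2, 11, score = 5)[, 1:10],
                mk_call(fm, 3, 12, score = 8.2)[, 1:10])
  expect_message(calls <- load_calls(rows, fm, 5, "frag1"), "dropped 1/3")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$score, c(5, 8.2))
  expect_equal(calls$bait_id, c(2L, 3L))

  set.seed(13)
  mixed <- do.call(rbind, lapply(1:100, function(i) {
    mk_call(fm, sample(40, 1), sample(40, 1), score = runif(1, 0, 10))[, 1:10]
  }))
  got <- suppressMessages(load_calls(mixed, fm, 5, "frag1"))
  expect_equal(nrow(got), sum(mixed$score >= 5))

  bad <- mk_call(fm, 2, 10)[, 1:10]
  bad$oe_end <- bad$oe_end + 1L
  expect_error(suppressMessages(load_calls(bad, fm, 5, "frag1")),
               "matches no frag_id")
})

test_that("resolution merging removes 4-fragment calls superseded by nested 1-fragment calls", {
  fm <- mk_fm()
  bins <- bin_fragments(fm, 4)
  c1 <- mk_call(fm, 2, 10)                      # frag 2 in bin 1, frag 10 in bin 3
  c4_nested <- mk_call(bins, 1, 3, res = "frag4")
  c4_other <- mk_call(bins, 5, 8, res = "frag4")
  ix <- merge_resolutions(c1, rbind(c4_nested, c4_other))
  expect_equal(nrow(ix), 2L)
  expect_setequal(ix$resolution, c("frag1", "frag4"))
  expect_false(any(ix$resolution == "frag4" & ix$bait_start == c4_nested$bait_start &
                     ix$oe_start == c4_nested$oe_start))
  # union without dedup keeps all three
  expect_equal(nrow(merge_resolutions(c1, rbind(c4_nested, c4_other),
                                      dedup = FALSE)), 3L)
  # disjoint anchor pairs -> simple union
  ix2 <- merge_resolutions(mk_call(fm, 2, 10), mk_call(bins, 6, 9, res = "frag4"))
  expect_equal(nrow(ix2), 2L)
})

test_that("merging matches a quadratic containment oracle and ignores input order", {
  set.seed(14)
  fm <- mk_fm(80, c("chr1", "chr2"))
  bins <- bin_fragments(fm, 4)
  for (rep in 1:10) {
    c1 <- do.call(rbind, lapply(1:15, function(i) {
      mk_call(fm, sample(fm$frag_id, 1), sample(fm$frag_id, 1))
    }))
    c4 <- do.call(rbind, lapply(1:15, function(i) {
      mk_call(bins, sample(bins$bin_id, 1), sample(bins$bin_id, 1),
              res = "frag4")
    }))
    ix <- merge_resolutions(c1, c4)
    contains <- function(outer_chr, os, oe, chr, s, e) {
      outer_chr == chr & os <= s & e <= oe
    }
    redundant <- vapply(seq_len(nrow(c4)), function(j) {
      any(contains(c4$bait_chr[j], c4$bait_start[j], c4$bait_end[j],
                   c1$bait_chr, c1$bait_start, c1$bait_end) &
            contains(c4$oe_chr[j], c4$oe_start[j], c4$oe_end[j],
                     c1$oe_chr, c1$oe_start, c1$oe_end))
    }, logical(1))
    expect_equal(nrow(ix), nrow(c1) + sum(!redundant))
    # permuting inputs leaves the merged output identical
    ixp <- merge_resolutions(c1[sample(nrow(c1)), ], c4[sample(nrow(c4)), ])
    expect_equal(as.data.frame(ix), as.data.frame(ixp))
  }
})

test_that("PIR derivation counts distinct contacted baits per other end", {
  fm <- mk_fm()
  ix <- merge_resolutions(mk_call(fm, 2, 10), mk_call(fm, 2, 10)[0, ])
  ps <- derive_pirs(ix)
  expect_equal(nrow(ps$pirs), 1L)
  expect_equal(ps$pirs$degree, 1L)

  many <- do.call(rbind, lapply(c(2, 4, 6, 8, 12), function(b) {
    mk_call(fm, b, 20)
  }))
  ps5 <- derive_pirs(merge_resolutions(many, many[0, ]))
  expect_equal(ps5$pirs$degree, 5L)

  set.seed(15)
  rand <- do.call(rbind, lapply(1:60, function(i) {
    mk_call(fm, sample(fm$frag_id, 1), sample(30:40, 1))
  }))
  ix <- merge_resolutions(rand, rand[0, ])
  ps <- derive_pirs(ix)
  # brute-force grouping oracle
  oe_key <- sprintf("%s:%d-%d", ix$oe_chr, ix$oe_start, ix$oe_end)
  bait_key <- sprintf("%s:%d-%d", ix$bait_chr, ix$bait_start, ix$bait_end)
  want <- vapply(split(bait_key, oe_key), function(b) length(unique(b)), 1L)
  got <- setNames(ps$pirs$degree,
                  sprintf("%s:%d-%d", ps$pirs$chrom, ps$pirs$start,
                          ps$pirs$end))
  expect_equal(got[names(want)], want)
  expect_equal(as.vector(ps$degree_histogram), as.vector(table(want)))
})

test_that("interactome statistics use midpoint distances and handle all-trans input", {
  fm <- mk_fm(40, c("chr1", "chr2"))
  # two cis pairs at midpoint distances ~10 kb is impossible on 6-bp frags;
  # verify the arithmetic on hand-made anchors instead
  calls <- data.frame(
    bait_chr = "chr1", bait_start = c(0L, 0L), bait_end = c(1000L, 1000L),
    bait_name = "b", oe_chr = "chr1", oe_start = c(10000L, 90000L),
    oe_end = c(11000L, 91000L), oe_name = "o", N_reads = 5L, score = 6,
    bait_id = 1L, oe_id = 2L, resolution = "frag1",
    stringsAsFactors = FALSE)
  ix <- merge_resolutions(calls, calls[0, ])
  st <- interactome_stats(ix)
  expect_equal(st$median_cis_bp, 50000)
  expect_equal(st$pct_trans, 0)

  tr <- calls
  tr$oe_chr <- "chr2"
  stt <- interactome_stats(merge_resolutions(tr, tr[0, ]))
  expect_equal(stt$pct_trans, 100)
  expect_true(is.na(stt$median_cis_bp))
  expect_error(interactome_stats(ix[0, ]), "no calls")

  # bait-to-bait flagging: %b2b and %non-bait oe are complementary
  genes <- data.frame(chrom = "chr1", tss = c(3L, 63L), strand = "+",
                      gene_id = c("G1", "G2"), symbol = c("A", "B"),
                      biotype = "protein_coding", stringsAsFactors = FALSE)
  baits <- design_baits(fm, genes)
  b2b <- merge_resolutions(rbind(mk_call(fm, 1, 11), mk_call(fm, 1, 20)),
                           mk_call(fm, 2, 10)[0, ], baits = baits)
  stb <- interactome_stats(b2b)
  expect_equal(stb$pct_bait_to_bait + 100 * mean(!b2b$bait_to_bait), 100)
})

test_that("trans calls never contribute a cis distance", {
  st <- default_study()
  res <- run_study_v2g(st)
  expect_true(all(is.na(res$ix$cis_distance[res$ix$is_trans])))
  expect_true(all(!is.na(res$ix$cis_distance[!res$ix$is_trans])))
})
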