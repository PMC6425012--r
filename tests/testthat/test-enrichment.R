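test_that("Welch test matches the closed-form expressions and stats::t.test", {
  x <- c(1, 2, 3, 4)
  y <- c(2, 3, 4, 5)
  w <- welch_test(x, y)
  se2 <- var(x) / 4 + var(y) / 4
  expect_equal(w$statistic, (mean(x) - mean(y)) / sqrt(se2))
  expect_equal(w$df, se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3))
  expect_equal(w$p, 2 * pt(-abs(w$statistic), w$df))

  # identical samples: t = 0, p = 1
  w0 <- welch_test(x, x)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)

  expect_error(welch_test(c(2, 2, 2), c(2, 2)), "degenerate")

  set.seed(17)
  for (i in 1:100) {
    a <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1))
    w <- welch_test(a, b)
    ref <- t.test(a, b)
    expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(w$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(w$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Welch test holds its nominal size under the null", {
  set.seed(18)
  rejections <- vapply(1:2000, function(i) {
    welch_test(rnorm(50), rnorm(50))$p < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

enrich_fixture <- function(n_pir = 60, n_cand = 600) {
  baits <- data.frame(chrom = "chr1",
                      start = seq(0L, 990000L, by = 100000L),
                      end = seq(0L, 990000L, by = 100000L) + 500L)
  mk <- function(n) {
    start <- sample.int(1000000L, n)
    data.frame(chrom = "chr1", start = start, end = start + 200L)
  }
  list(baits = baits, pirs = mk(n_pir), cands = mk(n_cand))
}

test_that("enrichment null behaves at the extremes of feature coverage", {
  set.seed(19)
  fx <- enrich_fixture()
  everything <- data.frame(chrom = "chr1", start = 0L, end = 2000000L)
  r <- feature_enrichment(fx$pirs, fx$cands, everything, fx$baits,
                          n_draws = 50, seed = 1)
  expect_equal(r$observed, nrow(fx$pirs))
  expect_equal(r$p_empirical, 1)
  expect_equal(r$z, 0)

  nothing <- data.frame(chrom = "chr9", start = 0L, end = 100L)
  r0 <- feature_enrichment(fx$pirs, fx$cands, nothing, fx$baits,
                           n_draws = 50, seed = 1)
  expect_equal(r0$observed, 0L)
  expect_equal(r0$p_empirical, 1)
})

test_that("planted feature enrichment is detected and runs are seed-reproducible", {
  set.seed(20)
  fx <- enrich_fixture()
  # features on 50% of PIRs, 5% of candidates
  on_pir <- fx$pirs[sample.int(nrow(fx$pirs), nrow(fx$pirs) / 2), ]
  on_cand <- fx$cands[sample.int(nrow(fx$cands), nrow(fx$cands) * 0.05), ]
  features <- rbind(on_pir, on_cand)
  r <- feature_enrichment(fx$pirs, fx$cands, features, fx$baits,
                          n_draws = 1000, seed = 7)
  expect_lte(r$p_empirical, 0.01)
  expect_gt(r$z, 2)

  r2 <- feature_enrichment(fx$pirs, fx$cands, features, fx$baits,
                           n_draws = 1000, seed = 7)
  expect_identical(r, r2)
  # p is never exactly 0 (add-one rule)
  expect_gt(r$p_empirical, 0)
  # feature order does not matter
  r3 <- feature_enrichment(fx$pirs, fx$cands,
                           features[rev(seq_len(nrow(features))), ],
                           fx$baits, n_draws = 1000, seed = 7)
  expect_equal(r3$observed, r$observed)
  expect_equal(r3$p_empirical, r$p_empirical)
})

mk_contact_study <- function(n_baits = 200, seed = 21) {
  set.seed(seed)
  open <- rep(c(TRUE, FALSE), each = n_baits / 2)
  # open promoters get double the loop rate to open other ends
  n_open_oe <- rpois(n_baits, ifelse(open, 8, 4))
  n_closed_oe <- rpois(n_baits, 3)
  rows <- list()
  oe_id <- 0L
  for (i in seq_len(n_baits)) {
    for (j in seq_len(n_open_oe[i] + n_closed_oe[i])) {
      oe_id <- oe_id + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        bait_chr = "chr1", bait_start = i * 1000L, bait_end = i * 1000L + 500L,
        bait_name = "b", oe_chr = "chr1", oe_start = 500000L + oe_id * 300L,
        oe_end = 500000L + oe_id * 300L + 200L, oe_name = "o",
        N_reads = 5L, score = 6, bait_id = i, oe_id = oe_id,
        resolution = "frag1", is_open_oe = j <= n_open_oe[i],
        stringsAsFactors = FALSE)
    }
  }
  calls <- do.call(rbind, rows)
  ix <- merge_resolutions(calls[, -ncol(calls)], calls[0, -ncol(calls)])
  bait_open <- data.frame(
    id = sprintf("chr1:%d-%d", seq_len(n_baits) * 1000L,
                 seq_len(n_baits) * 1000L + 500L),
    open = open)
  oe_open <- data.frame(
    id = sprintf("%s:%d-%d", calls$oe_chr, calls$oe_start, calls$oe_end),
    open = calls$is_open_oe)
  list(ix = ix, bait_open = bait_open, oe_open = oe_open, open = open)
}

test_that("contacts split by openness detect a planted promoter effect", {
  cs <- mk_contact_study()
  res <- contacts_by_group(cs$ix, cs$bait_open, cs$oe_open)
  expect_lt(res$test_open_oe$p, 0.05)
  expect_gt(res$test_open_oe$group_means[1], res$test_open_oe$group_means[2])

  # all promoters closed -> both open-vs-closed tests are skipped with warnings
  closed <- cs$bait_open
  closed$open <- FALSE
  w <- capture_warnings(res0 <- contacts_by_group(cs$ix, closed, cs$oe_open))
  expect_match(w, "skipped", all = TRUE)
  expect_length(w, 2L)
  expect_null(res0$test_total)
})

test_that("a deterministic expression-contact pairing gives rank correlation 1", {
  cs <- mk_contact_study(n_baits = 40)
  st <- interactome_stats(cs$ix, bait_open = cs$bait_open,
                          oe_open = cs$oe_open)
  expr <- data.frame(bait_key = st$contacts_per_bait$bait_key,
                     percentile = rank(st$contacts_per_bait$n_open_oe))
  res <- contacts_by_group(cs$ix, cs$bait_open, cs$oe_open, expression = expr)
  expect_equal(unname(res$spearman["open_promoters"]), 1)
  expect_equal(unname(res$spearman["closed_promoters"]), 1)
})

test_that("enrichment errors on an unfillable distance stratum", {
  fx <- enrich_fixture(n_pir = 30, n_cand = 30)
  # candidates all far from baits while PIRs span a range of distances
  far <- data.frame(chrom = "chr2", start = seq_len(30) * 1000L,
                    end = seq_len(30) * 1000L + 100L)
  expect_error(
    feature_enrichment(fx$pirs, far, far, fx$baits, n_draws = 10, seed = 1),
    "stratum")
})
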