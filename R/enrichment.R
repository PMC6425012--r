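#' Distance-matched permutation enrichment of PIRs for a feature set
#'
#' Tests whether promoter-interacting regions overlap a set of genomic
#' features more often than expected. The null is built by repeatedly drawing
#' `|PIR|` regions from a pool of candidate (non-significant) other ends,
#' stratified so that each draw matches the PIRs' distribution of
#' distance-to-nearest-bait deciles — interaction distance strongly
#' structures overlap rates, so the null must be distance-matched. Overlap is
#' counted by the 1-bp rule. Sampling within a stratum is with replacement.
#'
#' The empirical p-value uses the add-one rule
#' `p = (1 + #(null >= observed)) / (n_draws + 1)` and is therefore never 0;
#' `z = (observed - null_mean) / null_sd` (0 when the null is degenerate).
#'
#' @param pirs PIR intervals (`data.frame` `chrom`, `start`, `end`), e.g.
#'   `derive_pirs(ix)$pirs`.
#' @param candidates Candidate pool intervals (non-significant other ends),
#'   at least as many as PIRs.
#' @param features Feature intervals to test.
#' @param baits Bait intervals (`data.frame` `chrom`, `start`, `end` or a
#'   `bait_map`) used to compute distance-to-nearest-bait.
#' @param feature_label Label stored on the result.
#' @param n_draws Number of null draws (default 100).
#' @param seed Optional integer seed for reproducible draws.
#' @return List of class `enrichment_result`: `feature_label`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_empirical`, `n_draws`, `n_pirs`.
#' @export
feature_enrichment <- function(pirs, candidates, features, baits,
                               feature_label = "features", n_draws = 100L,
                               seed = NULL) {
  stopifnot(nrow(candidates) >= nrow(pirs), nrow(pirs) > 0)
  if (!is.null(seed)) set.seed(seed)
  bait_iv <- unique(data.frame(chrom = baits$chrom, start = baits$start,
                               end = baits$end, stringsAsFactors = FALSE))
  dist_to_bait <- function(x) {
    gr <- as_granges(x)
    hit <- suppressWarnings(
      GenomicRanges::distanceToNearest(gr, as_granges(bait_iv)))
    d <- rep(Inf, nrow(x))  # regions with no bait on their chromosome
    d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
    d
  }
  d_pir <- dist_to_bait(pirs)
  d_cand <- dist_to_bait(candidates)
  breaks <- unique(stats::quantile(d_pir, probs = seq(0, 1, by = 0.1),
                                   names = FALSE, type = 1))
  breaks[1] <- -Inf
  breaks[length(breaks)] <- Inf
  s_pir <- cut(d_pir, breaks, labels = FALSE)
  s_cand <- cut(d_cand, breaks, labels = FALSE)
  need <- table(s_pir)
  feat_gr <- as_granges(features)
  overlaps <- function(x) {
    if (!nrow(x) || !nrow(features)) return(logical(nrow(x)))
    suppressWarnings(IRanges::overlapsAny(as_granges(x), feat_gr))
  }
  observed <- sum(overlaps(pirs))
  cand_hit <- overlaps(candidates)
  cand_by_stratum <- split(seq_len(nrow(candidates)), s_cand)
  for (st in names(need)) {
    if (is.null(cand_by_stratum[[st]]) || !length(cand_by_stratum[[st]])) {
      stop(sprintf("empty candidate stratum for distance decile %s", st),
           call. = FALSE)
    }
  }
  null_counts <- vapply(seq_len(n_draws), function(i) {
    tot <- 0L
    for (st in names(need)) {
      pool <- cand_by_stratum[[st]]
      draw <- pool[sample.int(length(pool), need[[st]], replace = TRUE)]
      tot <- tot + sum(cand_hit[draw])
    }
    tot
  }, integer(1))
  null_mean <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  structure(list(feature_label = feature_label,
                 observed = observed,
                 null_mean = null_mean,
                 null_sd = null_sd,
                 z = if (isTRUE(null_sd > 0)) (observed - null_mean) / null_sd
                     else 0,
                 p_empirical = (1 + sum(null_counts >= observed)) /
                   (n_draws + 1),
                 n_draws = as.integer(n_draws),
                 n_pirs = nrow(pirs)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment of %s: observed %d / %d PIRs; null %.2f +/- %.2f; z = %.2f; p = %.4g (%d draws)\n",
              x$feature_label, x$observed, x$n_pirs, x$null_mean, x$null_sd,
              x$z, x$p_empirical, x$n_draws))
  invisible(x)
}

#' Write enrichment results as TSV
#' @param results An `enrichment_result` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    data.frame(feature_label = r$feature_label, observed = r$observed,
               null_mean = r$null_mean, null_sd = r$null_sd, z = r$z,
               p_empirical = r$p_empirical, n_draws = r$n_draws)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Two-sided test with `t = (mean_x - mean_y) / sqrt(s2x/nx + s2y/ny)` and
#' Welch–Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric samples (each of size >= 2 with finite variance; the
#'   test is degenerate when both variances are 0 and the means are equal).
#' @return List of class `welch_test`: `statistic`, `df`, `p`,
#'   `group_means`, `group_ns`.
#' @export
welch_test <- function(x, y) {
  nx <- length(x); ny <- length(y)
  stopifnot(nx >= 2, ny >= 2)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0 && mean(x) == mean(y)) {
    stop("degenerate: both samples have zero variance and equal means",
         call. = FALSE)
  }
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  structure(list(statistic = t, df = df,
                 p = 2 * stats::pt(-abs(t), df),
                 group_means = c(mean(x), mean(y)),
                 group_ns = c(nx, ny)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4f, df = %.2f, p = %.4g (means %.3f vs %.3f; n = %d, %d)\n",
              x$statistic, x$df, x$p, x$group_means[1], x$group_means[2],
              x$group_ns[1], x$group_ns[2]))
  invisible(x)
}

#' Contacts per bait stratified by promoter and other-end openness
#'
#' Counts, per baited promoter region, its interactions in total and those to
#' open other ends, then asks whether open promoters engage in more contacts
#' than inaccessible ones (Welch's t-test on each count type) and whether
#' more highly expressed genes have more open-to-open contacts (Spearman rank
#' correlation per promoter-openness stratum).
#'
#' @param ix An `interactome`.
#' @param bait_open `data.frame` (`id` = bait anchor key `chrom:start-end`,
#'   `open`) from [annotate_openness()] on the bait anchors.
#' @param oe_open `data.frame` (`id` = other-end anchor key, `open`).
#' @param expression Optional `data.frame` (`bait_key`, `percentile`) pairing
#'   each bait with the expression percentile of its gene.
#' @return List of class `contacts_by_group`: `table` (per-bait counts with
#'   openness), `test_total`, `test_open_oe` (Welch results or NULL when a
#'   stratum has < 2 baits, with a warning), `spearman` (per-stratum rank
#'   correlations, when expression is given).
#' @export
contacts_by_group <- function(ix, bait_open, oe_open, expression = NULL) {
  st <- interactome_stats(ix, bait_open = bait_open, oe_open = oe_open)
  cpb <- st$contacts_per_bait
  run_test <- function(col) {
    xs <- cpb[[col]][cpb$open %in% TRUE]
    ys <- cpb[[col]][cpb$open %in% FALSE]
    if (length(xs) < 2 || length(ys) < 2) {
      warning(sprintf("openness stratum with < 2 baits; %s test skipped", col),
              call. = FALSE)
      return(NULL)
    }
    welch_test(xs, ys)
  }
  out <- list(table = cpb,
              test_total = run_test("n_total"),
              test_open_oe = run_test("n_open_oe"))
  if (!is.null(expression)) {
    cpb$percentile <- expression$percentile[match(cpb$bait_key,
                                                  expression$bait_key)]
    out$spearman <- vapply(c(`TRUE` = TRUE, `FALSE` = FALSE), function(o) {
      sub <- cpb[cpb$open %in% o & !is.na(cpb$percentile), , drop = FALSE]
      if (nrow(sub) < 3) return(NA_real_)
      stats::cor(sub$percentile, sub$n_open_oe, method = "spearman")
    }, numeric(1))
    names(out$spearman) <- c("open_promoters", "closed_promoters")
  }
  class(out) <- "contacts_by_group"
  out
}

#' @export
print.contacts_by_group <- function(x, ...) {
  cat(sprintf("contacts_by_group: %d baits (%d open)\n",
              nrow(x$table), sum(x$table$open %in% TRUE)))
  if (!is.null(x$test_open_oe)) {
    cat("  open vs closed promoters, contacts to open other ends: ")
    print(x$test_open_oe)
  }
  if (!is.null(x$spearman)) {
    cat(sprintf("  Spearman (expression vs open-oe contacts): open %.3f, closed %.3f\n",
                x$spearman[1], x$spearman[2]))
  }
  invisible(x)
}
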