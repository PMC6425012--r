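#' Load significant interaction calls onto a fragment or bin map
#'
#' Filters raw ibed rows ([read_interactions()]) at the significance score
#' threshold (inclusive: a row at exactly the threshold is retained) and
#' resolves both anchors against the fragment map (1-fragment resolution) or
#' bin map (4-fragment resolution). Anchors must match map intervals exactly.
#'
#' @param rows Raw interaction `data.frame` with ibed columns.
#' @param map `fragment_map` (for `resolution = "frag1"`) or `bin_map`
#'   (`"frag4"`).
#' @param score_threshold Minimum retained score (default 5, the
#'   interaction caller's conventional cutoff).
#' @param resolution `"frag1"` or `"frag4"` tag stored on the calls.
#' @return `data.frame` of calls: anchor coordinates, `bait_id`, `oe_id`
#'   (map ids), `n_reads`, `score`, `resolution`. The number of sub-threshold
#'   rows dropped is reported via `message()`.
#' @export
load_calls <- function(rows, map, score_threshold = 5,
                       resolution = c("frag1", "frag4")) {
  resolution <- match.arg(resolution)
  keep <- rows$score >= score_threshold
  if (any(!keep)) {
    message(sprintf("load_calls: dropped %d/%d rows below score %s",
                    sum(!keep), nrow(rows), format(score_threshold)))
  }
  rows <- rows[keep, , drop = FALSE]
  id_col <- if (inherits(map, "bin_map")) "bin_id" else "frag_id"
  map_key <- sprintf("%s:%d-%d", map$chrom, map$start, map$end)
  resolve <- function(chr, s, e, side) {
    key <- sprintf("%s:%d-%d", chr, s, e)
    i <- match(key, map_key)
    if (anyNA(i)) {
      bad <- which(is.na(i))[1]
      stop(sprintf("row %d: %s anchor %s matches no %s interval",
                   bad, side, key[bad], id_col), call. = FALSE)
    }
    map[[id_col]][i]
  }
  out <- rows
  out$bait_id <- if (nrow(rows)) resolve(rows$bait_chr, rows$bait_start,
                                         rows$bait_end, "bait") else integer()
  out$oe_id <- if (nrow(rows)) resolve(rows$oe_chr, rows$oe_start,
                                       rows$oe_end, "oe") else integer()
  out$resolution <- rep(resolution, nrow(out))
  rownames(out) <- NULL
  out
}

anchor_gr <- function(calls, side) {
  GenomicRanges::GRanges(calls[[paste0(side, "_chr")]],
                         IRanges::IRanges(calls[[paste0(side, "_start")]] + 1L,
                                          calls[[paste0(side, "_end")]]))
}

#' Merge 1-fragment and 4-fragment resolution interaction calls
#'
#' Takes the union of the two call sets, each kept at its native resolution.
#' With `dedup = TRUE` (default) a 4-fragment call is considered redundant
#' and removed when some 1-fragment call has both anchors contained within
#' the corresponding bins of the 4-fragment call — the high-resolution call
#' supersedes it. Output order is deterministic (sorted by bait anchor, then
#' other end), independent of input order.
#'
#' @param calls1 Calls at 1-fragment resolution ([load_calls()]).
#' @param calls4 Calls at 4-fragment resolution.
#' @param dedup Remove 4-fragment calls superseded by nested 1-fragment
#'   calls?
#' @param baits Optional `bait_map`; when given, calls whose other end is (or
#'   contains) a baited fragment are flagged `bait_to_bait`.
#' @return An `interactome`: `data.frame` of calls with flags
#'   `bait_to_bait` (NA when `baits` not supplied), `is_trans` and
#'   `cis_distance` (midpoint to midpoint, NA for trans).
#' @export
merge_resolutions <- function(calls1, calls4, dedup = TRUE, baits = NULL) {
  if (dedup && nrow(calls4) && nrow(calls1)) {
    bait_in <- GenomicRanges::findOverlaps(anchor_gr(calls1, "bait"),
                                           anchor_gr(calls4, "bait"),
                                           type = "within")
    oe_in <- GenomicRanges::findOverlaps(anchor_gr(calls1, "oe"),
                                         anchor_gr(calls4, "oe"),
                                         type = "within")
    pair_key <- function(h) paste(S4Vectors::queryHits(h),
                                  S4Vectors::subjectHits(h))
    both <- intersect(pair_key(bait_in), pair_key(oe_in))
    redundant <- unique(as.integer(sub("^\\S+ ", "", both)))
    if (length(redundant)) calls4 <- calls4[-redundant, , drop = FALSE]
  }
  calls <- rbind(calls1, calls4)
  ord <- order(calls$bait_chr, calls$bait_start, calls$bait_end,
               calls$oe_chr, calls$oe_start, calls$oe_end, calls$resolution)
  calls <- calls[ord, , drop = FALSE]
  rownames(calls) <- NULL
  calls$is_trans <- calls$bait_chr != calls$oe_chr
  mid_b <- (calls$bait_start + calls$bait_end) / 2
  mid_o <- (calls$oe_start + calls$oe_end) / 2
  calls$cis_distance <- ifelse(calls$is_trans, NA_real_, abs(mid_b - mid_o))
  calls$bait_to_bait <- if (is.null(baits)) {
    rep(NA, nrow(calls))
  } else if (nrow(calls)) {
    first <- !duplicated(baits$frag_id)
    bait_gr <- GenomicRanges::GRanges(
      baits$chrom[first],
      IRanges::IRanges(baits$start[first] + 1L, baits$end[first]))
    IRanges::overlapsAny(anchor_gr(calls, "oe"), bait_gr)
  } else {
    logical(0)
  }
  class(calls) <- c("interactome", "data.frame")
  calls
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("interactome: %d calls (%d frag1, %d frag4), %.1f%% trans\n",
              nrow(x), sum(x$resolution == "frag1"),
              sum(x$resolution == "frag4"),
              if (nrow(x)) 100 * mean(x$is_trans) else 0))
  invisible(x)
}

#' Derive promoter-interacting regions (PIRs)
#'
#' Groups calls by their other-end anchor: every distinct other-end region
#' contacting at least one bait is a PIR, whether or not it is itself baited.
#' Reports the set of contacted baits per PIR (bait degree), the bait-degree
#' histogram, and the non-bait PIR subset when a `bait_map` is supplied.
#'
#' @param ix An `interactome` (or call `data.frame`).
#' @param baits Optional `bait_map` used to flag PIRs that are themselves
#'   baited.
#' @return List of class `pir_set`: `pirs` (`data.frame` `chrom`, `start`,
#'   `end`, `degree`, `is_bait`), `degree_histogram` (table), `baits_by_pir`
#'   (list of bait anchor keys per PIR).
#' @export
derive_pirs <- function(ix, baits = NULL) {
  if (!nrow(ix)) stop("no calls", call. = FALSE)
  oe_key <- sprintf("%s:%d-%d", ix$oe_chr, ix$oe_start, ix$oe_end)
  bait_key <- sprintf("%s:%d-%d", ix$bait_chr, ix$bait_start, ix$bait_end)
  by_pir <- lapply(split(bait_key, oe_key), unique)
  keys <- names(by_pir)
  parts <- regmatches(keys, regexec("^(.*):(\\d+)-(\\d+)$", keys))
  pirs <- data.frame(chrom = vapply(parts, `[`, "", 2),
                     start = as.integer(vapply(parts, `[`, "", 3)),
                     end = as.integer(vapply(parts, `[`, "", 4)),
                     degree = lengths(by_pir),
                     stringsAsFactors = FALSE)
  pirs$is_bait <- if (is.null(baits)) NA else {
    first <- !duplicated(baits$frag_id)
    bait_gr <- GenomicRanges::GRanges(
      baits$chrom[first],
      IRanges::IRanges(baits$start[first] + 1L, baits$end[first]))
    IRanges::overlapsAny(as_granges(pirs), bait_gr)
  }
  pirs <- pirs[order(pirs$chrom, pirs$start), , drop = FALSE]
  rownames(pirs) <- NULL
  structure(list(pirs = pirs,
                 degree_histogram = table(pirs$degree),
                 baits_by_pir = by_pir),
            class = "pir_set")
}

#' @export
print.pir_set <- function(x, ...) {
  cat(sprintf("pir_set: %d PIRs; %.1f%% contact a single bait\n",
              nrow(x$pirs), 100 * mean(x$pirs$degree == 1)))
  invisible(x)
}

#' Write a PIR set as BED with bait degree in the score column
#' @param ps A `pir_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pirs <- function(ps, path) {
  p <- ps$pirs
  out <- data.frame(chrom = p$chrom, start = p$start, end = p$end,
                    name = sprintf("PIR%04d", seq_len(nrow(p))),
                    score = p$degree,
                    strand = ".")
  write_intervals(out, path)
}

#' Summary statistics of a promoter interactome
#'
#' Computes the headline interactome numbers: call count, percentage of
#' bait-to-bait calls, percentage of trans calls, and the median cis
#' interaction distance (anchor midpoint to midpoint). When openness
#' annotations are supplied, also returns per-bait contact counts split by
#' promoter (bait) openness, total and restricted to open other ends.
#'
#' @param ix An `interactome` from [merge_resolutions()].
#' @param bait_open Optional `data.frame` (`id` = bait anchor key
#'   `chrom:start-end`, `open`) as from [annotate_openness()].
#' @param oe_open Optional `data.frame` (`id` = other-end anchor key,
#'   `open`).
#' @return List of class `interactome_stats`: `n_calls`, `pct_bait_to_bait`,
#'   `pct_trans`, `median_cis_bp` (NA when no cis calls) and, when openness
#'   is supplied, `contacts_per_bait` (`data.frame` `bait_key`, `open`,
#'   `n_total`, `n_open_oe`).
#' @export
interactome_stats <- function(ix, bait_open = NULL, oe_open = NULL) {
  if (!nrow(ix)) stop("no calls", call. = FALSE)
  cis <- ix$cis_distance[!ix$is_trans]
  out <- list(n_calls = nrow(ix),
              pct_bait_to_bait = if (all(is.na(ix$bait_to_bait))) NA_real_
                                 else 100 * mean(ix$bait_to_bait),
              pct_trans = 100 * mean(ix$is_trans),
              median_cis_bp = if (length(cis)) stats::median(cis) else NA_real_)
  if (!is.null(bait_open)) {
    bait_key <- sprintf("%s:%d-%d", ix$bait_chr, ix$bait_start, ix$bait_end)
    oe_key <- sprintf("%s:%d-%d", ix$oe_chr, ix$oe_start, ix$oe_end)
    oe_is_open <- if (is.null(oe_open)) rep(NA, nrow(ix))
                  else oe_open$open[match(oe_key, oe_open$id)]
    tot <- table(bait_key)
    open_oe <- table(factor(bait_key[oe_is_open %in% TRUE],
                            levels = names(tot)))
    cpb <- data.frame(bait_key = names(tot),
                      open = bait_open$open[match(names(tot), bait_open$id)],
                      n_total = as.integer(tot),
                      n_open_oe = as.integer(open_oe),
                      stringsAsFactors = FALSE)
    rownames(cpb) <- NULL
    out$contacts_per_bait <- cpb
  }
  class(out) <- "interactome_stats"
  out
}

#' @export
print.interactome_stats <- function(x, ...) {
  cat(sprintf("interactome: %d calls\n", x$n_calls))
  cat(sprintf("  bait-to-bait: %s%%\n",
              if (is.na(x$pct_bait_to_bait)) "NA"
              else sprintf("%.1f", x$pct_bait_to_bait)))
  cat(sprintf("  trans: %.2f%%\n", x$pct_trans))
  cat(sprintf("  median cis distance: %s\n",
              if (is.na(x$median_cis_bp)) "NA (no cis calls)"
              else sprintf("%.1f kb", x$median_cis_bp / 1000)))
  invisible(x)
}
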