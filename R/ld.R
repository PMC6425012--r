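#' Construct a phased haplotype panel
#'
#' @param variants `data.frame` with columns `id`, `chrom`, `pos` (1-based),
#'   one row per variant, ids unique.
#' @param mat Integer matrix of 0/1 alleles, haplotypes in rows, variants in
#'   columns (column order matching `variants`).
#' @return A `haplotype_panel` object.
#' @export
haplotype_panel <- function(variants, mat) {
  stopifnot(is.data.frame(variants),
            all(c("id", "chrom", "pos") %in% names(variants)),
            nrow(variants) == ncol(mat), nrow(mat) >= 2,
            all(mat %in% c(0L, 1L)))
  if (anyDuplicated(variants$id)) {
    stop("variant ids must be unique within a panel", call. = FALSE)
  }
  colnames(mat) <- variants$id
  structure(list(variants = variants, mat = mat), class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d haplotypes x %d variants\n",
              nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

panel_column <- function(panel, id) {
  if (!id %in% colnames(panel$mat)) {
    stop(sprintf("variant '%s' absent from panel", id), call. = FALSE)
  }
  col <- panel$mat[, id]
  if (length(unique(col)) < 2) {
    stop(sprintf("undefined r²: variant '%s' is monomorphic", id),
         call. = FALSE)
  }
  col
}

#' Pairwise linkage-disequilibrium r-squared
#'
#' Computes r2 between two biallelic variants from phased haplotypes as
#' `(p_AB - p_A p_B)^2 / (p_A (1 - p_A) p_B (1 - p_B))`, with `p_AB` the
#' haplotype frequency of carrying the alternate allele at both loci and
#' `p_A`, `p_B` the alternate-allele frequencies. Symmetric in its
#' arguments, invariant to relabelling alleles at either locus, and equal to
#' 1 for identical or strictly complementary allele columns.
#'
#' @param panel A `haplotype_panel`.
#' @param a,b Variant ids present (and polymorphic) in the panel.
#' @return r2 in `[0, 1]`.
#' @export
compute_r2 <- function(panel, a, b) {
  x <- panel_column(panel, a)
  y <- panel_column(panel, b)
  pa <- mean(x)
  pb <- mean(y)
  pab <- mean(x == 1L & y == 1L)
  (pab - pa * pb)^2 / (pa * (1 - pa) * pb * (1 - pb))
}

#' Expand GWAS sentinels into LD proxy sets
#'
#' For each sentinel, returns every panel variant within `window_bp` whose r2
#' with the sentinel is at or above `threshold` (inclusive, so proxies at
#' exactly the threshold are kept). The sentinel is always reported as its
#' own proxy with r2 = 1. Output order is deterministic: by sentinel, then
#' proxy position, then id. Monomorphic panel variants are skipped (r2 is
#' undefined for them).
#'
#' @param panel A `haplotype_panel`.
#' @param sentinels Character vector of sentinel variant ids, or a
#'   `data.frame` with columns `id` and optionally `gwas_set`.
#' @param threshold Minimum r2 (default 0.8; the liberal companion analysis
#'   uses 0.4).
#' @param window_bp Search radius around the sentinel in bp (default 500 kb).
#' @return `data.frame` with columns `sentinel_id`, `proxy_id`, `r2`,
#'   `chrom`, `pos`, `gwas_set`.
#' @export
find_proxies <- function(panel, sentinels, threshold = 0.8,
                         window_bp = 500000L) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.data.frame(sentinels)) {
    sets <- if ("gwas_set" %in% names(sentinels)) sentinels$gwas_set
            else rep(NA_character_, nrow(sentinels))
    ids <- sentinels$id
  } else {
    ids <- as.character(sentinels)
    sets <- rep(NA_character_, length(ids))
  }
  missing <- setdiff(ids, panel$variants$id)
  if (length(missing)) {
    stop("sentinel(s) absent from panel: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  v <- panel$variants
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    s <- ids[i]
    srow <- v[v$id == s, ]
    cand <- v[v$chrom == srow$chrom & abs(v$pos - srow$pos) <= window_bp, ,
              drop = FALSE]
    r2 <- vapply(cand$id, function(p) {
      if (p == s) return(1)
      tryCatch(compute_r2(panel, s, p), error = function(e) NA_real_)
    }, numeric(1))
    keep <- !is.na(r2) & r2 >= threshold
    cand <- cand[keep, , drop = FALSE]
    r2 <- r2[keep]
    ord <- order(cand$pos, cand$id)
    out[[i]] <- data.frame(sentinel_id = s, proxy_id = cand$id[ord],
                           r2 = r2[ord], chrom = cand$chrom[ord],
                           pos = cand$pos[ord], gwas_set = sets[i],
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Attach genomic positions to a proxy table
#'
#' Pre-computed proxy tables ([read_proxies()]) carry only identifiers; this
#' joins chromosome and position from a variant table so the proxies can be
#' placed on the fragment map.
#'
#' @param proxies Proxy `data.frame` with a `proxy_id` column.
#' @param variants `data.frame` with columns `id`, `chrom`, `pos`.
#' @return `proxies` with `chrom` and `pos` columns added.
#' @export
add_variant_positions <- function(proxies, variants) {
  i <- match(proxies$proxy_id, variants$id)
  if (anyNA(i)) {
    stop("no position for proxy id(s): ",
         paste(unique(proxies$proxy_id[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  proxies$chrom <- variants$chrom[i]
  proxies$pos <- as.integer(variants$pos[i])
  proxies
}
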