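#' Verify the packaged fixtures
#'
#' Checks every file listed in the fixture manifest against its md5 checksum
#' and re-validates the schema of the packaged results table (46 loci, 95
#' distinct proxy ids, 81 distinct gene symbols).
#'
#' @param quiet Suppress the per-fixture message?
#' @return Named logical vector (TRUE = pass), invisibly; a mismatch raises
#'   an error naming the file.
#' @export
verify_fixtures <- function(quiet = FALSE) {
  manifest_path <- system.file("extdata", "manifest.json",
                               package = "capv2g", mustWork = TRUE)
  manifest <- jsonlite::read_json(manifest_path)
  results <- logical(0)
  for (fx in manifest$fixtures) {
    for (f in fx$files) {
      path <- system.file("extdata", f$name, package = "capv2g")
      if (!nzchar(path)) stop("fixture file missing: ", f$name, call. = FALSE)
      md5 <- unname(tools::md5sum(path))
      ok <- identical(md5, f$md5)
      if (!ok) {
        stop(sprintf("fixture checksum mismatch for %s (expected %s, got %s)",
                     f$name, f$md5, md5), call. = FALSE)
      }
      results[f$name] <- ok
      if (!quiet) message(sprintf("fixture ok: %s [%s]", f$name, fx$provenance))
    }
  }
  t1 <- load_table1()
  counts <- summarize_loci(table1_links(t1))$counts
  if (counts$n_loci != 46L || counts$n_distinct_proxies != 95L ||
        counts$n_distinct_genes != 81L) {
    stop("results-table fixture counts do not validate (want 46/95/81)",
         call. = FALSE)
  }
  results["table1 counts 46/95/81"] <- TRUE
  invisible(results)
}

#' Path to the packaged pre-built synthetic study
#' @return Directory of the small checked-in synthetic study (provenance:
#'   synthetic; generated by [generate_study()] at a reduced size).
#' @export
synthetic_study_path <- function() {
  system.file("extdata", "synthetic_study", package = "capv2g",
              mustWork = TRUE)
}
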