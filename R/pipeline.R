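#' Run the full classification pipeline
#'
#' From a raw count matrix and sample sheet: size factors, normalized
#' counts, per-group summary, the five contrasts (internal NB Wald test,
#' or externally computed tables via `contrasts`), the consistent OSKM
#' response call, the up-/down-reprogramome, the per-gene PIANO table
#' and the category summary. When a gene-set collection is supplied,
#' overrepresentation is tested for each PIANO category against the
#' full gene universe as reference.
#'
#' @param counts Count matrix (see [read_count_matrix()]).
#' @param samples Validated sample sheet (see [read_sample_sheet()]).
#' @param thresholds A [piano_thresholds()] object.
#' @param gene_sets Optional [read_gene_sets()] collection.
#' @param contrasts Optional externally computed contrast list (see
#'   [import_contrasts()]); replaces the internal test.
#' @param pseudocount Fold-change pseudocount for the internal test.
#' @param log2_pseudocount Pseudocount for the exported log2 matrix.
#' @return List of class `piano_result` with components
#'   `size_factors`, `normalized`, `group_summary`, `contrasts`,
#'   `response`, `reprogramome`, `piano_table`, `summary`,
#'   `log2_matrix` and (optionally) `enrichment`.
#' @export
piano_run <- function(counts, samples, thresholds = piano_thresholds(),
                      gene_sets = NULL, contrasts = NULL,
                      pseudocount = 0.5, log2_pseudocount = 1) {
  samples <- validate_sample_sheet(as.data.frame(samples), counts = counts)
  f <- size_factors(counts)
  n <- normalize_counts(counts, f)
  summ <- group_summary(n, samples, thresholds)
  if (is.null(contrasts)) {
    contrasts <- run_contrasts(n, samples, pseudocount = pseudocount)
  } else {
    ok <- vapply(contrasts, function(cr) identical(cr$gene_id, summ$gene_id),
                 logical(1))
    if (!all(ok)) stop_format("supplied contrasts are not aligned with the counts")
  }
  reprog <- build_reprogramome(summ, contrasts$E_vs_F, thresholds)
  resp <- consistent_response(contrasts, summ, thresholds)
  tab <- classify_all(summ, resp, reprog, thresholds)
  res <- list(size_factors = f, normalized = n, group_summary = summ,
              contrasts = contrasts, response = resp, reprogramome = reprog,
              piano_table = tab,
              summary = piano_summarize(tab, resp, reprog, contrasts,
                                        thresholds),
              log2_matrix = log2_matrix(n, log2_pseudocount))
  if (!is.null(gene_sets)) {
    universe <- tab$gene_id
    enr <- lapply(setdiff(PIANO_CATEGORIES, c("TRANSITIONAL", "OUT_OF_SCOPE")),
                  function(cc) {
      q <- tab$gene_id[tab$category == cc]
      if (length(q) == 0) return(NULL)
      out <- overrepresentation(q, universe, gene_sets, thresholds)
      if (nrow(out)) out$query <- cc
      out
    })
    enr <- do.call(rbind, enr)
    res$enrichment <- enr %||% data.frame()
  }
  class(res) <- "piano_result"
  res
}

#' @export
print.piano_result <- function(x, ...) {
  cat(sprintf("piano_result: %d genes, %d samples\n",
              nrow(x$piano_table), length(x$size_factors)))
  print(x$summary)
  invisible(x)
}

#' Write a `piano_result` to disk
#'
#' Convenience wrapper around [write_results()].
#'
#' @param res A `piano_result`.
#' @param out_dir Output directory.
#' @return Invisibly, the file manifest.
#' @export
write_piano_result <- function(res, out_dir) {
  stopifnot(inherits(res, "piano_result"))
  write_results(list(
    piano_table = res$piano_table,
    category_counts = summary_table(res$summary),
    enrichment = res$enrichment,
    log2_matrix = res$log2_matrix,
    size_factors = res$size_factors,
    contrasts = res$contrasts), out_dir)
}
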