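#' Gene-set overrepresentation testing
#'
#' One-sided Fisher's exact test (hypergeometric upper tail
#' `P(X >= k)`) of a query gene list against a reference universe, for
#' every gene set in a collection. Query genes outside the reference are
#' dropped with a logged count; each set is intersected with the
#' reference first and sets smaller than `min_set_size` after
#' intersection are skipped. For each tested set the table reports the
#' set size within the reference (`K`), the observed overlap (`k`), the
#' expected overlap `n * K / N`, the fold enrichment `k / expected`
#' (reported unrounded), the Fisher p-value and its BH q-value across
#' tested sets, plus a significance flag at `enrich_fdr`. Rows are
#' sorted by q then p.
#'
#' @param query Character vector of query genes.
#' @param reference Character vector, the gene universe.
#' @param sets A [read_gene_sets()] collection (or named list).
#' @param thresholds A [piano_thresholds()] object (`enrich_fdr` used).
#' @param min_set_size Sets smaller than this after intersection with
#'   the reference are not tested; singleton sets give degenerate tests,
#'   hence the default of 2.
#' @return `data.frame` with one row per tested set.
#' @export
overrepresentation <- function(query, reference, sets,
                               thresholds = piano_thresholds(),
                               min_set_size = 2) {
  if (length(query) == 0 || length(reference) == 0)
    stop_format("query and reference must be non-empty")
  reference <- unique(reference)
  query <- unique(query)
  outside <- setdiff(query, reference)
  if (length(outside)) {
    piano_log(sprintf("%d query gene(s) outside the reference dropped",
                      length(outside)))
    query <- intersect(query, reference)
  }
  if (length(query) == 0) stop_format("no query gene is in the reference")
  N <- length(reference)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], reference)
    K <- length(members)
    if (K < min_set_size) return(NULL)
    k <- length(intersect(query, members))
    expected <- n * K / N
    data.frame(set_name = nm, K = K, k = k, n = n, N = N,
               expected = expected, fold = k / expected,
               p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(set_name = character(0), K = integer(0), k = integer(0),
                      n = integer(0), N = integer(0), expected = numeric(0),
                      fold = numeric(0), p = numeric(0), q = numeric(0),
                      significant = logical(0)))
  }
  rows$q <- bh_adjust(rows$p)
  rows$significant <- rows$q < thresholds$enrich_fdr
  rows <- rows[order(rows$q, rows$p, rows$set_name), ]
  rownames(rows) <- NULL
  rows
}
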