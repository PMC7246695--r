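#' Analysis thresholds
#'
#' Bundle of the cutoffs that drive reprogramome membership, differential
#' expression calls and category assignment. The defaults are the study
#' conditions: a gene counts as expressed in a cell type only when every
#' replicate has a normalized count above `expr_min`; differential calls
#' require at least a `de_fold` change at `q_max`; the highly enriched
#' pools (whose non-responders become the refractory categories) require
#' at least `high_fold` enrichment and a mean above `high_expr_min`;
#' overshoot categories require `over_fold` relative to the starting
#' fibroblast level.
#'
#' @param expr_min Normalized-count expression threshold (strict `>`).
#' @param high_expr_min Normalized-count threshold for the highly
#'   enriched pools (strict `>`).
#' @param de_fold Minimum fold change for a differential call (inclusive
#'   `>=` on the ratio scale).
#' @param high_fold Minimum enrichment fold for the highly enriched pools.
#' @param over_fold Fold relative to fibroblasts used by the overshoot
#'   categories.
#' @param q_max Maximum BH-adjusted p-value for a differential call
#'   (strict `<`).
#' @param enrich_fdr FDR cutoff for gene-set overrepresentation
#'   significance flags.
#'
#' @return A validated list of class `piano_thresholds`.
#' @examples
#' piano_thresholds()
#' piano_thresholds(de_fold = 1.5, q_max = 0.05)
#' @export
piano_thresholds <- function(expr_min = 50, high_expr_min = 500,
                             de_fold = 2, high_fold = 5, over_fold = 4,
                             q_max = 0.01, enrich_fdr = 0.05) {
  t <- structure(
    list(expr_min = expr_min, high_expr_min = high_expr_min,
         de_fold = de_fold, high_fold = high_fold, over_fold = over_fold,
         q_max = q_max, enrich_fdr = enrich_fdr),
    class = "piano_thresholds")
  validate_thresholds(t)
}

validate_thresholds <- function(t) {
  num <- vapply(t, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop_format("thresholds must be single finite numbers; offending: %s",
                paste(names(t)[!num], collapse = ", "))
  }
  if (any(unlist(t) <= 0)) {
    stop_format("all thresholds must be strictly positive")
  }
  if (t$de_fold <= 1) stop_format("de_fold must exceed 1")
  if (t$high_fold < t$de_fold) stop_format("high_fold must be >= de_fold")
  if (t$over_fold < t$de_fold) stop_format("over_fold must be >= de_fold")
  t
}

#' Read thresholds from a YAML configuration file
#'
#' The file must contain a `thresholds` block whose keys mirror the
#' arguments of [piano_thresholds()]; absent keys keep their defaults,
#' unknown keys are an error.
#'
#' @param path Path to a YAML file.
#' @return A `piano_thresholds` object.
#' @export
read_thresholds <- function(path) {
  cfg <- yaml::read_yaml(path)
  blk <- cfg$thresholds %||% list()
  known <- names(formals(piano_thresholds))
  bad <- setdiff(names(blk), known)
  if (length(bad)) {
    stop_format("unknown threshold field(s) in %s: %s", path,
                paste(bad, collapse = ", "))
  }
  do.call(piano_thresholds, blk)
}
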