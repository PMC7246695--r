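#' Build the up- and down-reprogramome
#'
#' The upreprogramome holds genes that must be upregulated to ESC levels
#' for successful reprogramming: expressed in ESCs (every ESC replicate
#' strictly above `expr_min`), at least `de_fold` higher in ESCs than in
#' fibroblasts by group means, and significant in the ESC-vs-fibroblast
#' contrast (`q < q_max`). The downreprogramome is the mirror with the
#' fibroblast side expressed. The highly enriched pools (`up_high`,
#' `down_high`) additionally require at least `high_fold` enrichment and
#' an enriched-side mean strictly above `high_expr_min`; they do not
#' additionally require DE significance -- they are defined by fold and
#' abundance only, and their members without a consistent OSKM response
#' become the refractory categories. A gene with a zero mean on the
#' depleted side counts as infinitely enriched, subject to the expressed
#' rule on the enriched side.
#'
#' @param summ Output of [group_summary()].
#' @param e_vs_f The `E_vs_F` contrast table (with `q`).
#' @param thresholds A [piano_thresholds()] object.
#' @return Object of class `reprogramome`: list with character vectors
#'   `up_set`, `down_set`, `up_high`, `down_high` and an `evidence`
#'   data frame (per-gene folds, q and membership flags).
#' @export
build_reprogramome <- function(summ, e_vs_f, thresholds = piano_thresholds()) {
  if (!identical(summ$gene_id, e_vs_f$gene_id))
    stop_format("group summary and E_vs_F contrast are not aligned")
  t <- thresholds
  up_fold <- fold_ratio(summ$E_mean, summ$F_mean)
  down_fold <- fold_ratio(summ$F_mean, summ$E_mean)
  sig <- e_vs_f$q < t$q_max
  in_up <- summ$expressed_ESC & up_fold >= t$de_fold & sig
  in_down <- summ$expressed_FIB & down_fold >= t$de_fold & sig
  in_up_high <- up_fold >= t$high_fold & summ$E_mean > t$high_expr_min
  in_down_high <- down_fold >= t$high_fold & summ$F_mean > t$high_expr_min
  stopifnot(!any(in_up & in_down))
  evidence <- data.frame(
    gene_id = summ$gene_id,
    E_mean = summ$E_mean, F_mean = summ$F_mean,
    up_fold = up_fold, down_fold = down_fold,
    q_E_vs_F = e_vs_f$q,
    expressed_FIB = summ$expressed_FIB, expressed_ESC = summ$expressed_ESC,
    in_up_set = in_up, in_down_set = in_down,
    in_up_high = in_up_high, in_down_high = in_down_high,
    row.names = NULL)
  structure(list(up_set = summ$gene_id[in_up],
                 down_set = summ$gene_id[in_down],
                 up_high = summ$gene_id[in_up_high],
                 down_high = summ$gene_id[in_down_high],
                 evidence = evidence),
            class = "reprogramome")
}

#' Candidate pools for the refractory categories
#'
#' Returns the two highly enriched pools whose members lacking any
#' consistent OSKM response are scored as refractory. The analysis
#' concentrates on these pools because genes with higher expression and
#' larger expression gaps between fibroblasts and PSCs are assumed to
#' matter more for reprogramming than weakly expressed, mildly enriched
#' ones.
#'
#' @param reprog A `reprogramome` object.
#' @return List with `up_high` and `down_high` character vectors.
#' @export
highly_enriched_candidates <- function(reprog) {
  stopifnot(inherits(reprog, "reprogramome"))
  list(up_high = reprog$up_high, down_high = reprog$down_high)
}

#' @export
print.reprogramome <- function(x, ...) {
  cat(sprintf(paste0("reprogramome: %d up / %d down; highly enriched ",
                     "pools: %d up / %d down\n"),
              length(x$up_set), length(x$down_set),
              length(x$up_high), length(x$down_high)))
  invisible(x)
}
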