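#' @name piano_categories
#' @title The PIANO category space
#' @description Every gene receives exactly one of 14 labels: the 12
#'   PIANO categories -- proper, insufficient and refractory
#'   up/down-reprogramming plus the six aberrant types (wrong, unwanted
#'   and overshooting up/down) -- and two bookkeeping labels:
#'   `TRANSITIONAL` for responsive genes whose timepoints disagree or
#'   that escape every category guard, and `OUT_OF_SCOPE` for genes with
#'   no consistent response outside the highly enriched pools.
#' @export
PIANO_CATEGORIES <- c(
  "PROPER_UP", "PROPER_DOWN",
  "INSUFFICIENT_UP", "INSUFFICIENT_DOWN",
  "REFRACTORY_UP", "REFRACTORY_DOWN",
  "WRONG_UP", "WRONG_DOWN",
  "UNWANTED_UP", "UNWANTED_DOWN",
  "OVER_UP", "OVER_DOWN",
  "TRANSITIONAL", "OUT_OF_SCOPE")

#' Classify a single gene
#'
#' Scalar reference implementation of the PIANO decision tree; the
#' vectorized [classify_all()] must agree with it gene for gene.
#'
#' The tree, for a consistent UP response: a gene that should have gone
#' down (downreprogramome member) is `WRONG_UP`; an upreprogramome
#' member is `OVER_UP` when the OSKM level overshoots at both
#' timepoints (at least `de_fold` above the ESC level and `over_fold`
#' above the fibroblast level), `INSUFFICIENT_UP` when it stays at least
#' `de_fold` below the ESC level at both timepoints, `PROPER_UP` when it
#' lies within `de_fold` of the ESC level at both timepoints, and
#' `TRANSITIONAL` when the timepoints disagree; a gene in neither set
#' whose fibroblast and ESC levels differ by less than `de_fold` is
#' `UNWANTED_UP`; anything else is `TRANSITIONAL`. DOWN mirrors this,
#' with the proper-down guard accepting either ESC-like levels or
#' shut-off below the expression threshold. Genes with no consistent
#' response are `REFRACTORY_UP`/`REFRACTORY_DOWN` when they belong to
#' the highly enriched pools and `OUT_OF_SCOPE` otherwise.
#'
#' @param F_mean,E_mean,R48_mean,R72_mean Group means of normalized
#'   counts for the gene.
#' @param response `"UP"`, `"DOWN"` or `"NONE"` (see
#'   [consistent_response()]).
#' @param in_up_set,in_down_set,in_up_high,in_down_high Membership flags
#'   from [build_reprogramome()].
#' @param thresholds A [piano_thresholds()] object.
#' @return Single category string.
#' @export
classify_gene <- function(F_mean, E_mean, R48_mean, R72_mean, response,
                          in_up_set, in_down_set,
                          in_up_high = FALSE, in_down_high = FALSE,
                          thresholds = piano_thresholds()) {
  if (in_up_set && in_down_set)
    stop_format("gene is in both sub-reprogramomes; upstream invariant broken")
  t <- thresholds
  r <- c(R48_mean, R72_mean)
  both <- function(cond) all(cond)
  if (response == "UP") {
    if (in_down_set) return("WRONG_UP")
    if (in_up_set) {
      if (both(r >= t$de_fold * E_mean) && both(r >= t$over_fold * F_mean))
        return("OVER_UP")
      if (both(r <= E_mean / t$de_fold)) return("INSUFFICIENT_UP")
      if (both(r > E_mean / t$de_fold & r < t$de_fold * E_mean))
        return("PROPER_UP")
      return("TRANSITIONAL")
    }
    if (sym_fold(E_mean, F_mean) < t$de_fold) return("UNWANTED_UP")
    return("TRANSITIONAL")
  }
  if (response == "DOWN") {
    if (in_up_set) return("WRONG_DOWN")
    if (in_down_set) {
      if (both(r <= E_mean / t$de_fold) && both(r <= F_mean / t$over_fold))
        return("OVER_DOWN")
      if (both(r >= t$de_fold * E_mean & r > t$expr_min))
        return("INSUFFICIENT_DOWN")
      if (both(r < t$de_fold * E_mean | r <= t$expr_min))
        return("PROPER_DOWN")
      return("TRANSITIONAL")
    }
    if (sym_fold(E_mean, F_mean) < t$de_fold) return("UNWANTED_DOWN")
    return("TRANSITIONAL")
  }
  if (in_up_high) return("REFRACTORY_UP")
  if (in_down_high) return("REFRACTORY_DOWN")
  "OUT_OF_SCOPE"
}

#' Classify every gene
#'
#' Vectorized PIANO classification over an aligned gene universe.
#'
#' @param summ Output of [group_summary()].
#' @param response Output of [consistent_response()].
#' @param reprog Output of [build_reprogramome()].
#' @param thresholds A [piano_thresholds()] object.
#' @return `data.frame` (the per-gene PIANO table) with the category,
#'   the evidence used (means, response, membership flags) and the id of
#'   the rule that fired.
#' @export
classify_all <- function(summ, response, reprog,
                         thresholds = piano_thresholds()) {
  ev <- reprog$evidence
  if (!identical(summ$gene_id, response$gene_id) ||
      !identical(summ$gene_id, ev$gene_id))
    stop_format("inputs are not aligned on the same gene universe")
  if (any(ev$in_up_set & ev$in_down_set))
    stop_format("gene in both sub-reprogramomes; upstream invariant broken")
  t <- thresholds
  F_ <- summ$F_mean; E_ <- summ$E_mean
  r48 <- summ$R48_mean; r72 <- summ$R72_mean
  up <- response$response == "UP"
  down <- response$response == "DOWN"
  none <- !up & !down
  flat_EF <- sym_fold(E_, F_) < t$de_fold

  over_up <- r48 >= t$de_fold * E_ & r72 >= t$de_fold * E_ &
    r48 >= t$over_fold * F_ & r72 >= t$over_fold * F_
  insuf_up <- r48 <= E_ / t$de_fold & r72 <= E_ / t$de_fold
  proper_up <- r48 > E_ / t$de_fold & r48 < t$de_fold * E_ &
    r72 > E_ / t$de_fold & r72 < t$de_fold * E_

  over_down <- r48 <= E_ / t$de_fold & r72 <= E_ / t$de_fold &
    r48 <= F_ / t$over_fold & r72 <= F_ / t$over_fold
  insuf_down <- r48 >= t$de_fold * E_ & r48 > t$expr_min &
    r72 >= t$de_fold * E_ & r72 > t$expr_min
  proper_down <- (r48 < t$de_fold * E_ | r48 <= t$expr_min) &
    (r72 < t$de_fold * E_ | r72 <= t$expr_min)

  cat_ <- rep("TRANSITIONAL", nrow(summ))
  rule <- rep("responsive_unclassified", nrow(summ))

  set_rule <- function(sel, category, id) {
    cat_[sel] <<- category
    rule[sel] <<- id
  }
  set_rule(up & ev$in_down_set, "WRONG_UP", "up_in_down_set")
  in_up_only <- up & !ev$in_down_set & ev$in_up_set
  set_rule(in_up_only & over_up, "OVER_UP", "up_overshoot_both_t")
  set_rule(in_up_only & !over_up & insuf_up, "INSUFFICIENT_UP",
           "up_below_esc_gap_both_t")
  set_rule(in_up_only & !over_up & !insuf_up & proper_up, "PROPER_UP",
           "up_within_esc_band_both_t")
  set_rule(up & !ev$in_down_set & !ev$in_up_set & flat_EF, "UNWANTED_UP",
           "up_no_ef_difference")

  set_rule(down & ev$in_up_set, "WRONG_DOWN", "down_in_up_set")
  in_down_only <- down & !ev$in_up_set & ev$in_down_set
  set_rule(in_down_only & over_down, "OVER_DOWN", "down_overshoot_both_t")
  set_rule(in_down_only & !over_down & insuf_down, "INSUFFICIENT_DOWN",
           "down_above_esc_gap_both_t")
  set_rule(in_down_only & !over_down & !insuf_down & proper_down,
           "PROPER_DOWN", "down_reached_esc_or_off_both_t")
  set_rule(down & !ev$in_up_set & !ev$in_down_set & flat_EF,
           "UNWANTED_DOWN", "down_no_ef_difference")

  set_rule(none & ev$in_up_high, "REFRACTORY_UP", "no_response_up_high")
  set_rule(none & !ev$in_up_high & ev$in_down_high, "REFRACTORY_DOWN",
           "no_response_down_high")
  set_rule(none & !ev$in_up_high & !ev$in_down_high, "OUT_OF_SCOPE",
           "no_response_outside_pools")

  data.frame(
    gene_id = summ$gene_id,
    category = factor(cat_, levels = PIANO_CATEGORIES),
    response = response$response,
    F_mean = F_, E_mean = E_, R48_mean = r48, R72_mean = r72,
    in_up_set = ev$in_up_set, in_down_set = ev$in_down_set,
    in_up_high = ev$in_up_high, in_down_high = ev$in_down_high,
    rule_id = rule,
    row.names = NULL)
}

#' Summarize category counts and reporting arithmetic
#'
#' Tallies the per-gene PIANO table into category counts, the derived
#' totals (proper, insufficient, refractory and the six-way aberrant
#' total) and the percentages the analysis reports, each with its
#' denominator recorded. Percentages are rounded half-up to one decimal;
#' a zero denominator yields `NA` rather than 0. The auxiliary counts
#' are the consistently up-/downregulated gene tallies (`n_up`,
#' `n_down`) and, when contrast tables are supplied, the union-style
#' differential counts over the two timepoints (a gene counts as
#' union-DE versus a baseline if it passes the fold and q cutoffs at 48
#' or 72 h in both no-virus and GFP baselines for that direction at the
#' same timepoint); the union counts are reporting statistics only and
#' play no role in classification.
#'
#' @param tab PIANO table from [classify_all()].
#' @param response Output of [consistent_response()].
#' @param reprog Output of [build_reprogramome()] (for the refractory
#'   denominators).
#' @param contrasts Optional list from [run_contrasts()]; enables the
#'   union-DE counts.
#' @param thresholds A [piano_thresholds()] object.
#' @return List of class `piano_summary` with `counts` (named integer
#'   vector over all 14 labels), `totals`, `percentages` (data frame
#'   with value, numerator, denominator) and `aux`.
#' @export
piano_summarize <- function(tab, response, reprog, contrasts = NULL,
                            thresholds = piano_thresholds()) {
  counts <- table(factor(tab$category, levels = PIANO_CATEGORIES))
  counts <- stats::setNames(as.integer(counts), PIANO_CATEGORIES)
  totals <- c(
    proper_total = counts[["PROPER_UP"]] + counts[["PROPER_DOWN"]],
    insufficient_total = counts[["INSUFFICIENT_UP"]] + counts[["INSUFFICIENT_DOWN"]],
    refractory_total = counts[["REFRACTORY_UP"]] + counts[["REFRACTORY_DOWN"]],
    aberrant_total = counts[["WRONG_UP"]] + counts[["WRONG_DOWN"]] +
      counts[["UNWANTED_UP"]] + counts[["UNWANTED_DOWN"]] +
      counts[["OVER_UP"]] + counts[["OVER_DOWN"]])
  n_up <- sum(response$response == "UP")
  n_down <- sum(response$response == "DOWN")
  pct <- function(num, den) {
    if (den == 0) NA_real_ else round_half_up(100 * num / den, 1)
  }
  percentages <- data.frame(
    quantity = c("proper_up_of_upregulated", "proper_down_of_downregulated",
                 "refractory_up_of_up_high", "refractory_down_of_down_high"),
    numerator = c(counts[["PROPER_UP"]], counts[["PROPER_DOWN"]],
                  counts[["REFRACTORY_UP"]], counts[["REFRACTORY_DOWN"]]),
    denominator = c(n_up, n_down,
                    length(reprog$up_high), length(reprog$down_high)))
  percentages$value <- mapply(pct, percentages$numerator,
                              percentages$denominator)
  aux <- list(n_up = n_up, n_down = n_down)
  if (!is.null(contrasts)) {
    aux$union_de_vs_F <- union_de_count(contrasts, "R48_vs_F", "R72_vs_F",
                                        thresholds)
    aux$union_de_vs_G <- union_de_count(contrasts, "R48_vs_G48",
                                        "R72_vs_G72", thresholds)
  }
  structure(list(counts = counts, totals = totals,
                 percentages = percentages, aux = aux),
            class = "piano_summary")
}

# genes differential (either direction) vs one baseline at >= 1 timepoint
union_de_count <- function(contrasts, c48, c72, thresholds) {
  hit <- function(cr) {
    cr$q < thresholds$q_max & abs(cr$log2fc) >= log2(thresholds$de_fold)
  }
  sum(hit(contrasts[[c48]]) | hit(contrasts[[c72]]))
}

#' @export
print.piano_summary <- function(x, ...) {
  cat("PIANO category counts:\n")
  print(x$counts)
  cat("totals:\n")
  print(x$totals)
  cat("percentages:\n")
  print(x$percentages, row.names = FALSE)
  invisible(x)
}

#' Reporting percentage
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal --
#' the convention used for all reported category shares. A zero
#' denominator yields `NA`.
#'
#' @param numerator,denominator Single counts.
#' @return Percentage on the 0-100 scale.
#' @examples
#' report_percentage(366, 946) # 38.7
#' @export
report_percentage <- function(numerator, denominator) {
  if (denominator == 0) return(NA_real_)
  round_half_up(100 * numerator / denominator, 1)
}

#' Flatten a summary into a two-column table for export
#'
#' @param s A `piano_summary`.
#' @return `data.frame` with `quantity` and `value`.
#' @export
summary_table <- function(s) {
  stopifnot(inherits(s, "piano_summary"))
  base <- data.frame(
    quantity = c(names(s$counts), names(s$totals),
                 s$percentages$quantity,
                 names(s$aux)),
    value = c(unname(s$counts), unname(s$totals),
              s$percentages$value,
              as.numeric(unlist(s$aux))))
  base
}
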