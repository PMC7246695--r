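PIANO_CONTRASTS <- c("E_vs_F", "R48_vs_F", "R72_vs_F",
                     "R48_vs_G48", "R72_vs_G72")

#' Gene-wise negative-binomial dispersion by method of moments
#'
#' For each gene, the moment estimator `(s^2 - mu) / mu^2` is computed
#' within every group of at least two samples and the estimates are
#' pooled by a degrees-of-freedom weighted average, floored at
#' `alpha_floor`. Pooling across all design groups (9 residual df in the
#' default study design) gives a markedly better-behaved estimate than
#' the 2-4 df available inside a single two-group contrast, which is why
#' [run_contrasts()] estimates dispersion once from the full design and
#' shares it across its five contrasts. No shrinkage toward a
#' mean-dispersion trend is applied.
#'
#' @param n Normalized count matrix.
#' @param groups List of character vectors of sample ids, one per group.
#' @param alpha_floor Lower bound on the dispersion.
#' @return Numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(n, groups, alpha_floor = 1e-8) {
  num <- rep(0, nrow(n))
  den <- 0
  for (ids in groups) {
    if (length(ids) < 2) next
    sub <- n[, ids, drop = FALSE]
    mu <- rowMeans(sub)
    s2 <- apply(sub, 1, stats::var)
    a <- ifelse(mu > 0, (s2 - mu) / mu^2, 0)
    w <- length(ids) - 1
    num <- num + w * a
    den <- den + w
  }
  if (den == 0) stop_format("dispersion needs at least one group with >= 2 samples")
  pmax(alpha_floor, num / den)
}

#' Two-group negative-binomial Wald test
#'
#' Per gene, with group means `muA`, `muB` of normalized counts:
#' `log2fc = log2((muB + pc) / (muA + pc))`; the standard error of the
#' log2 difference follows by the delta method under the NB variance
#' `mu + alpha * mu^2`, giving
#' `SE^2 = [(muA + a muA^2) / (nA (muA+pc)^2) + (muB + a muB^2) / (nB (muB+pc)^2)] / ln(2)^2`;
#' `z = log2fc / SE` and `p` is the two-sided normal tail. A gene with
#' zero counts in both groups gets `log2fc = 0, p = 1`. This test is a
#' declared simplification of full DE engines (no dispersion shrinkage
#' toward a trend, no fold-change moderation); externally computed DE
#' tables can be substituted via [import_contrasts()].
#'
#' @param n Normalized count matrix.
#' @param groupA,groupB Character vectors of sample ids (reference is
#'   `groupA`: positive `log2fc` means higher in `groupB`).
#' @param pseudocount Added inside the fold change so silenced genes get
#'   finite fold changes; default 0.5.
#' @param dispersion Optional per-gene dispersion vector (e.g. from
#'   [estimate_dispersion()] on the full design). When `NULL`, the
#'   method-of-moments estimate pooled across the two groups is used; a
#'   group of size 1 is allowed but then relies entirely on the other
#'   group's dispersion (or the floor) and is flagged with a message.
#' @param alpha_floor Dispersion floor.
#' @return `data.frame` with `gene_id`, `log2fc`, `p` (no `q`; adjust
#'   per contrast with [bh_adjust()]).
#' @export
nb_wald_test <- function(n, groupA, groupB, pseudocount = 0.5,
                         dispersion = NULL, alpha_floor = 1e-8) {
  if (length(groupA) == 0 || length(groupB) == 0)
    stop_format("empty group in contrast")
  miss <- setdiff(c(groupA, groupB), colnames(n))
  if (length(miss)) stop_format("unknown sample(s): %s", paste(miss, collapse = ", "))
  if (length(groupA) < 2 || length(groupB) < 2) {
    piano_log("a contrast group has a single sample; dispersion relies on ",
              "the other group (or the floor)", level = "warn")
  }
  a_mat <- n[, groupA, drop = FALSE]
  b_mat <- n[, groupB, drop = FALSE]
  muA <- rowMeans(a_mat)
  muB <- rowMeans(b_mat)
  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion(n, list(groupA, groupB), alpha_floor)
  }
  a <- pmax(alpha_floor, dispersion)
  pc <- pseudocount
  log2fc <- log2((muB + pc) / (muA + pc))
  varA <- (muA + a * muA^2) / (length(groupA) * (muA + pc)^2)
  varB <- (muB + a * muB^2) / (length(groupB) * (muB + pc)^2)
  se <- sqrt(varA + varB) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  zero <- muA == 0 & muB == 0
  log2fc[zero] <- 0
  p[zero] <- 1
  data.frame(gene_id = rownames(n), log2fc = log2fc, p = p,
             row.names = NULL)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjustment `q(i) = min over j >= i of p(j) * n / j` in rank
#' order, capped at 1; ties keep input order stable. Inputs outside
#' `[0, 1]` are an error.
#'
#' @param p Vector of p-values.
#' @return Vector of q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop_format("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run the study's five contrasts
#'
#' Computes `E_vs_F`, `R48_vs_F`, `R72_vs_F`, `R48_vs_G48` and
#' `R72_vs_G72`, each against the same gene universe, with a single
#' design-wide dispersion estimate shared across contrasts and BH
#' q-values computed within each contrast. GFP baselines are matched by
#' timepoint rather than pooled, controlling for time in culture.
#'
#' @param n Normalized count matrix.
#' @param sheet Validated sample sheet.
#' @param pseudocount Fold-change pseudocount, see [nb_wald_test()].
#' @param alpha_floor Dispersion floor.
#' @return Named list of five contrast `data.frame`s
#'   (`gene_id`, `log2fc`, `p`, `q`, `contrast`).
#' @export
run_contrasts <- function(n, sheet, pseudocount = 0.5, alpha_floor = 1e-8) {
  grp <- list(F = design_group(sheet, "FIB"),
              E = design_group(sheet, "ESC"),
              R48 = design_group(sheet, "OSKM", 48),
              R72 = design_group(sheet, "OSKM", 72),
              G48 = design_group(sheet, "GFP", 48),
              G72 = design_group(sheet, "GFP", 72))
  disp <- estimate_dispersion(n, grp, alpha_floor)
  spec <- list(E_vs_F = c("F", "E"),
               R48_vs_F = c("F", "R48"),
               R72_vs_F = c("F", "R72"),
               R48_vs_G48 = c("G48", "R48"),
               R72_vs_G72 = c("G72", "R72"))
  out <- lapply(names(spec), function(nm) {
    ab <- spec[[nm]]
    res <- nb_wald_test(n, grp[[ab[1]]], grp[[ab[2]]],
                        pseudocount = pseudocount, dispersion = disp,
                        alpha_floor = alpha_floor)
    res$q <- bh_adjust(res$p)
    res$contrast <- nm
    res
  })
  names(out) <- names(spec)
  out
}

#' Import externally computed contrast tables
#'
#' Fidelity path for DE results produced by an external engine. Each TSV
#' must have columns `gene_id`, `log2fc`, `p`, `q`. Genes present in
#' `gene_ids` but absent from a table are filled in as non-significant
#' (`log2fc = 0, p = q = 1`) with a logged count.
#'
#' @param paths Named character vector of file paths; names must be the
#'   five contrast labels of `run_contrasts()`.
#' @param gene_ids Optional gene universe to align every table to.
#' @return Named list of five contrast `data.frame`s.
#' @export
import_contrasts <- function(paths, gene_ids = NULL) {
  miss <- setdiff(PIANO_CONTRASTS, names(paths))
  if (length(miss)) stop_format("missing contrast table(s): %s",
                                paste(miss, collapse = ", "))
  out <- lapply(PIANO_CONTRASTS, function(nm) {
    df <- utils::read.table(paths[[nm]], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "log2fc", "p", "q")
    absent <- setdiff(need, colnames(df))
    if (length(absent)) stop_format("%s: missing column(s): %s", paths[[nm]],
                                    paste(absent, collapse = ", "))
    df <- df[, need]
    if (!is.null(gene_ids)) {
      extra <- setdiff(gene_ids, df$gene_id)
      if (length(extra)) {
        piano_log(sprintf("%s: %d gene(s) absent from import treated as non-significant",
                          nm, length(extra)))
        df <- rbind(df, data.frame(gene_id = extra, log2fc = 0, p = 1, q = 1))
      }
      df <- df[match(gene_ids, df$gene_id), ]
      rownames(df) <- NULL
    }
    df$contrast <- nm
    df
  })
  names(out) <- PIANO_CONTRASTS
  out
}

#' Consistent transcriptional response to OSKM
#'
#' A gene responds UP only when all four OSKM contrasts (vs naive
#' fibroblasts and vs the timepoint-matched GFP controls, at both 48 and
#' 72 h) show `log2fc >= log2(de_fold)` with `q < q_max`; DOWN is the
#' mirror; anything else is NONE. Genes whose expression stays below the
#' expression threshold both with and without OSKM (max of fibroblast,
#' GFP and OSKM group means under `expr_min`) are forced to NONE even if
#' their fold change exceeds the cutoff, since fold changes between two
#' unexpressed states are not meaningful.
#'
#' @param contrasts List from [run_contrasts()] or [import_contrasts()]
#'   (the `E_vs_F` slot may be present; only the four OSKM contrasts are
#'   used).
#' @param summ Output of [group_summary()].
#' @param thresholds A [piano_thresholds()] object.
#' @return `data.frame` with `gene_id`, `response` (UP/DOWN/NONE) and
#'   `sub_threshold`.
#' @export
consistent_response <- function(contrasts, summ,
                                thresholds = piano_thresholds()) {
  need <- setdiff(PIANO_CONTRASTS[-1], names(contrasts))
  if (length(need)) stop_format("missing contrast(s): %s",
                                paste(need, collapse = ", "))
  lfc_cut <- log2(thresholds$de_fold)
  up <- rep(TRUE, nrow(summ))
  down <- rep(TRUE, nrow(summ))
  for (nm in PIANO_CONTRASTS[-1]) {
    cr <- contrasts[[nm]]
    if (!identical(cr$gene_id, summ$gene_id))
      stop_format("contrast %s is not aligned with the group summary", nm)
    sig <- cr$q < thresholds$q_max
    up <- up & sig & cr$log2fc >= lfc_cut
    down <- down & sig & cr$log2fc <= -lfc_cut
  }
  sub <- pmax(summ$F_mean, summ$G48_mean, summ$G72_mean,
              summ$R48_mean, summ$R72_mean) < thresholds$expr_min
  response <- ifelse(sub, "NONE", ifelse(up, "UP", ifelse(down, "DOWN", "NONE")))
  data.frame(gene_id = summ$gene_id, response = response,
             sub_threshold = sub, row.names = NULL)
}
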