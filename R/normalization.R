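#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over usable genes of
#' the ratio of that sample's count to the gene's geometric mean across
#' all samples (the pseudo-reference). Usable genes are those with a
#' strictly positive count in every sample. The median of an even-length
#' ratio vector is the arithmetic mean of the two central values.
#' Factors are reported as raw medians, deliberately not rescaled to
#' unit geometric mean: rescaling would change absolute normalized
#' counts and therefore the meaning of the expression thresholds (50 and
#' 500 normalized counts).
#'
#' @param m Count matrix (genes x samples).
#' @return Named numeric vector of positive per-sample factors.
#' @export
size_factors <- function(m) {
  m <- validate_count_matrix(m)
  usable <- rowSums(m > 0) == ncol(m)
  if (!any(usable)) {
    stop_format(paste0("no gene has positive counts in every sample; ",
                       "median-of-ratios is undefined (a pseudo-reference ",
                       "fallback is not implemented)"))
  }
  mm <- m[usable, , drop = FALSE]
  loggeo <- rowMeans(log(mm))
  f <- apply(mm / exp(loggeo), 2, stats::median)
  stopifnot(all(f > 0))
  f
}

#' Divide counts by size factors
#'
#' @param m Count matrix.
#' @param f Named size-factor vector covering every sample of `m`.
#' @return Numeric matrix of normalized counts, same dimnames and order.
#' @export
normalize_counts <- function(m, f) {
  m <- validate_count_matrix(m)
  miss <- setdiff(colnames(m), names(f))
  if (length(miss)) stop_format("missing size factor for sample(s): %s",
                                paste(miss, collapse = ", "))
  if (any(f[colnames(m)] <= 0)) stop_format("size factors must be > 0")
  sweep(m, 2, f[colnames(m)], "/")
}

#' Per-group expression summary
#'
#' Computes, for every gene, the arithmetic mean of normalized counts in
#' each design group -- fibroblasts (`F_mean`), ESCs (`E_mean`), OSKM at
#' 48 and 72 h (`R48_mean`, `R72_mean`) and the GFP controls (`G48_mean`,
#' `G72_mean`) -- together with the replicate-level expressed flags: a
#' gene is expressed in fibroblasts (or ESCs) only when *every*
#' replicate is strictly above `expr_min`, so a single replicate at or
#' below the threshold vetoes the flag no matter how large the mean is.
#'
#' @param n Normalized count matrix.
#' @param sheet Validated sample sheet.
#' @param thresholds A [piano_thresholds()] object.
#' @return `data.frame` with one row per gene.
#' @export
group_summary <- function(n, sheet, thresholds = piano_thresholds()) {
  grp_mean <- function(ids) {
    if (length(ids) == 1) n[, ids] else rowMeans(n[, ids, drop = FALSE])
  }
  fib <- design_group(sheet, "FIB")
  esc <- design_group(sheet, "ESC")
  out <- data.frame(
    gene_id = rownames(n),
    F_mean = grp_mean(fib),
    E_mean = grp_mean(esc),
    R48_mean = grp_mean(design_group(sheet, "OSKM", 48)),
    R72_mean = grp_mean(design_group(sheet, "OSKM", 72)),
    G48_mean = grp_mean(design_group(sheet, "GFP", 48)),
    G72_mean = grp_mean(design_group(sheet, "GFP", 72)),
    expressed_FIB = rowSums(n[, fib, drop = FALSE] > thresholds$expr_min) ==
      length(fib),
    expressed_ESC = rowSums(n[, esc, drop = FALSE] > thresholds$expr_min) ==
      length(esc),
    row.names = NULL)
  out
}

#' Log2 transform for visualization export
#'
#' Classification never uses the log matrix; this is only the matrix
#' behind heat maps, ladder plots and box plots.
#'
#' @param n Normalized count matrix.
#' @param pseudocount Added before taking logs; default 1 so that a zero
#'   count maps to 0.
#' @return Matrix of `log2(value + pseudocount)`.
#' @export
log2_matrix <- function(n, pseudocount = 1) {
  if (pseudocount < 0) stop_format("pseudocount must be >= 0")
  if (pseudocount == 0 && any(n <= 0)) {
    stop_format("log2 of zero: supply a positive pseudocount")
  }
  log2(n + pseudocount)
}
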