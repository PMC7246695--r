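# Independent oracles and fixture builders shared by the suite.
# Each oracle deliberately re-derives its quantity from first principles
# (loops, explicit sums) rather than reusing package code paths.

options(pianoseq.log_level = "quiet")

# brute-force median-of-ratios: explicit geometric mean, manual median
sf_oracle <- function(m) {
  geo <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  keep <- apply(m, 1, function(r) all(r > 0))
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    ratios <- sort(m[keep, j] / geo[keep])
    k <- length(ratios)
    out[j] <- if (k %% 2 == 1) ratios[(k + 1) / 2] else
      (ratios[k / 2] + ratios[k / 2 + 1]) / 2
  }
  names(out) <- colnames(m)
  out
}

# literal BH step-up in rank order
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  running <- Inf
  for (i in rev(seq_len(n))) {
    running <- min(running, p[o[i]] * n / i)
    q[o[i]] <- min(1, running)
  }
  q
}

# hypergeometric upper-tail P(X >= k) by explicit summation
hyper_tail_oracle <- function(k, K, N, n) {
  js <- seq(max(0, k), min(K, n))
  if (length(js) == 0) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# NB Wald p-value recomputed scalar-style from the defining formulas
wald_oracle <- function(muA, muB, nA, nB, alpha, pc) {
  lfc <- log2((muB + pc) / (muA + pc))
  se2 <- (muA + alpha * muA^2) / (nA * (muA + pc)^2) +
    (muB + alpha * muB^2) / (nB * (muB + pc)^2)
  se <- sqrt(se2) / log(2)
  list(log2fc = lfc, p = 2 * pnorm(-abs(lfc / se)))
}

# small count matrix fixture: 3 genes x 2 samples
tiny_counts <- function() {
  m <- matrix(c(10L, 20L, 40L, 20L, 40L, 80L), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  m
}

write_tiny_counts <- function(path, sep = "\t") {
  m <- tiny_counts()
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

# the full study design sheet used across tests
study_sheet <- function() {
  validate_sample_sheet(data.frame(
    sample_id = c(paste0("FIB_", 1:4), paste0("ESC_", 1:3),
                  "OSKM_48_1", "OSKM_48_2", "OSKM_72_1", "OSKM_72_2",
                  "GFP_48_1", "GFP_48_2", "GFP_72_1", "GFP_72_2"),
    state = c(rep("FIB", 4), rep("ESC", 3), rep("OSKM", 4), rep("GFP", 4)),
    timepoint_h = c(rep(0L, 7), 48L, 48L, 72L, 72L, 48L, 48L, 72L, 72L),
    replicate = c(1:4, 1:3, 1:2, 1:2, 1:2, 1:2)))
}

# verify that every truth row satisfies its category's inequalities with
# at least the configured margin -- an independent re-statement of the
# planting contract
check_truth_margins <- function(truth, t = piano_thresholds(), m = 1.25) {
  de <- t$de_fold
  ok <- logical(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    r <- truth[i, ]
    R <- c(r$R48, r$R72)
    ok[i] <- switch(
      r$category,
      PROPER_UP = r$E / r$F >= m * de && r$E > m * t$expr_min &&
        all(R > r$E / (de / m) & R < r$E * (de / m)) &&
        all(R / r$F >= m * de),
      PROPER_DOWN = r$F / r$E >= m * de && r$F > m * t$expr_min &&
        all(R < r$E * (de / m) | R <= t$expr_min / m) &&
        all(r$F / R >= m * de),
      INSUFFICIENT_UP = r$E / r$F >= m * de && r$E > m * t$expr_min &&
        all(R >= m * de * r$F) && all(R <= r$E / (m * de)),
      INSUFFICIENT_DOWN = r$F / r$E >= m * de && r$F > m * t$expr_min &&
        all(r$F / R >= m * de) && all(R >= m * de * r$E) &&
        all(R > m * t$expr_min),
      REFRACTORY_UP = r$E / r$F >= m * t$high_fold &&
        r$E > m * t$high_expr_min &&
        all(pmax(R / r$F, r$F / R) <= de / m),
      REFRACTORY_DOWN = r$F / r$E >= m * t$high_fold &&
        r$F > m * t$high_expr_min &&
        all(pmax(R / r$F, r$F / R) <= de / m),
      WRONG_UP = r$F / r$E >= m * de && r$F > m * t$expr_min &&
        all(R >= m * de * r$F),
      WRONG_DOWN = r$E / r$F >= m * de && r$E > m * t$expr_min &&
        all(R <= r$F / (m * de)),
      UNWANTED_UP = r$E == r$F && all(R >= m * de * r$F),
      UNWANTED_DOWN = r$E == r$F && all(R <= r$F / (m * de)),
      OVER_UP = r$E / r$F >= m * de && r$E > m * t$expr_min &&
        all(R >= m * de * r$E) && all(R >= m * t$over_fold * r$F),
      OVER_DOWN = r$F / r$E >= m * de && r$F > m * t$expr_min &&
        all(R <= r$E / (m * de)) && all(R <= r$F / (m * t$over_fold)),
      OUT_OF_SCOPE = TRUE,
      FALSE)
  }
  ok
}
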