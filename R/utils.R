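# Small shared helpers. Nothing here is exported.

# Ratio a/b with the conventions used throughout the classifier:
# b == 0 & a > 0 -> Inf (fully enriched); a == b == 0 -> 1 (no difference).
fold_ratio <- function(a, b) {
  out <- ifelse(b > 0, a / b, ifelse(a > 0, Inf, 1))
  out
}

# Symmetric fold: max(a/b, b/a), same zero conventions.
sym_fold <- function(a, b) {
  pmax(fold_ratio(a, b), fold_ratio(b, a))
}

# round() in R is banker's rounding; reported percentages use half-up.
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

piano_log <- function(..., level = "info") {
  lv <- getOption("pianoseq.log_level", "info")
  ranks <- c(debug = 1L, info = 2L, warn = 3L, quiet = 4L)
  if (ranks[[level]] >= ranks[[lv]]) {
    message(sprintf("[pianoseq] %s", paste0(...)))
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_format <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
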