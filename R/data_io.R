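#' Read a gene-by-sample count matrix
#'
#' Expects the first column to hold gene identifiers and the header row
#' sample identifiers. Counts must be non-negative integers (quantifier
#' output that is fractional upstream must be rounded half-up before
#' input; the negative-binomial model downstream assumes integer counts).
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return An integer matrix with gene ids as rownames and sample ids as
#'   colnames, row order preserved.
#' @export
read_count_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop_format("%s: need a gene-id column plus >=1 sample", path)
  genes <- df[[1]]
  samples <- colnames(df)[-1]
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop_format("duplicated gene id(s): %s",
                               paste(unique(dup), collapse = ", "))
  dup <- samples[duplicated(samples)]
  if (length(dup)) stop_format("duplicated sample id(s): %s",
                               paste(unique(dup), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df))))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(genes, samples))
  bad <- which(is.na(vals) | vals < 0 | vals != floor(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_format("non-integer or negative count at gene '%s', sample '%s'",
                genes[bad[1, 1]], samples[bad[1, 2]])
  }
  storage.mode(vals) <- "integer"
  validate_count_matrix(vals)
}

validate_count_matrix <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
    stop_format("count matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(m))) stop_format("duplicated gene ids")
  if (anyDuplicated(colnames(m))) stop_format("duplicated sample ids")
  if (any(m < 0) || any(m != floor(m)))
    stop_format("counts must be non-negative integers")
  m
}

PIANO_STATES <- c("FIB", "ESC", "OSKM", "GFP")

#' Read and validate a sample sheet
#'
#' The sheet binds each sequencing sample to its cell state and
#' timepoint. Required columns: `sample_id`, `state` (one of FIB, ESC,
#' OSKM, GFP), `timepoint_h` (0 for FIB/ESC; 48 or 72 for OSKM/GFP) and
#' `replicate`. The study design needs at least 2 fibroblast and 2 ESC
#' replicates and, for each of OSKM and GFP, at least one sample at each
#' of 48 and 72 h; replicate counts per treatment group beyond presence
#' are not enforced.
#'
#' @param path Path to a TSV file.
#' @param counts Optional count matrix; if given, sheet and matrix sample
#'   sets must match exactly.
#' @return A validated `data.frame` of class `piano_design`.
#' @export
read_sample_sheet <- function(path, counts = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  validate_sample_sheet(df, counts = counts)
}

#' Validate a sample-sheet data frame
#'
#' @param df A data frame with columns `sample_id`, `state`,
#'   `timepoint_h`, `replicate`.
#' @inheritParams read_sample_sheet
#' @return `df` with class `piano_design` prepended.
#' @export
validate_sample_sheet <- function(df, counts = NULL) {
  need <- c("sample_id", "state", "timepoint_h", "replicate")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop_format("sample sheet missing column(s): %s",
                                paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop_format("duplicated sample_id in sheet: %s",
                paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$state), PIANO_STATES)
  if (length(bad)) stop_format("unknown state label(s): %s",
                               paste(bad, collapse = ", "))
  df$timepoint_h <- as.integer(df$timepoint_h)
  df$replicate <- as.integer(df$replicate)
  if (any(df$replicate < 1 | is.na(df$replicate)))
    stop_format("replicate must be a positive integer")
  tr <- df$state %in% c("OSKM", "GFP")
  if (any(!df$timepoint_h[tr] %in% c(48L, 72L)))
    stop_format("OSKM/GFP samples must be at 48 or 72 h; offender: %s",
                df$sample_id[tr & !df$timepoint_h %in% c(48L, 72L)][1])
  if (any(df$timepoint_h[!tr] != 0L))
    stop_format("FIB/ESC samples must have timepoint_h = 0; offender: %s",
                df$sample_id[!tr & df$timepoint_h != 0L][1])
  if (sum(df$state == "FIB") < 2) stop_format("design error: need >= 2 FIB replicates")
  if (sum(df$state == "ESC") < 2) stop_format("design error: need >= 2 ESC replicates")
  for (st in c("OSKM", "GFP")) {
    for (tp in c(48L, 72L)) {
      if (!any(df$state == st & df$timepoint_h == tp))
        stop_format("design error: missing group %s@%dh", st, tp)
    }
  }
  if (!is.null(counts)) {
    if (!setequal(df$sample_id, colnames(counts)) ||
        nrow(df) != ncol(counts))
      stop_format("sample sheet and count matrix disagree on samples")
  }
  piano_log(sprintf(
    "design: %d FIB, %d ESC, OSKM %d@48h/%d@72h, GFP %d@48h/%d@72h",
    sum(df$state == "FIB"), sum(df$state == "ESC"),
    sum(df$state == "OSKM" & df$timepoint_h == 48),
    sum(df$state == "OSKM" & df$timepoint_h == 72),
    sum(df$state == "GFP" & df$timepoint_h == 48),
    sum(df$state == "GFP" & df$timepoint_h == 72)))
  class(df) <- c("piano_design", "data.frame")
  df
}

# sample ids of one design group
design_group <- function(sheet, state, timepoint = NULL) {
  sel <- sheet$state == state
  if (!is.null(timepoint)) sel <- sel & sheet$timepoint_h == timepoint
  sheet$sample_id[sel]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#' Members are deduplicated within each set; unknown genes are retained
#' at load time and only intersected with the reference universe when a
#' test is run.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of class
#'   `piano_gene_sets`, with a `descriptions` attribute.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3) {
      stop_format("GMT line %d: need name, description and >= 1 member", i)
    }
    nm <- f[[1]]
    if (nm %in% names(sets)) stop_format("GMT line %d: duplicated set name '%s'", i, nm)
    sets[[nm]] <- unique(f[-(1:2)])
    desc[[nm]] <- f[[2]]
  }
  structure(sets, descriptions = desc, class = c("piano_gene_sets", "list"))
}

#' Write pipeline result tables
#'
#' Writes the per-gene category table, category counts, enrichment table
#' (when present) and the log2 visualization matrix as TSV files, and
#' returns a manifest of every file written with its data row count.
#' Output is deterministic: re-running on the same inputs reproduces the
#' files byte for byte.
#'
#' @param tables Named list; recognized names are `piano_table`,
#'   `category_counts`, `enrichment`, `log2_matrix`, `size_factors`,
#'   plus any contrast tables under `contrasts`.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, a data frame manifest (`file`, `n_rows`).
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_format("cannot create output directory %s", out_dir)
  }
  manifest <- data.frame(file = character(0), n_rows = integer(0))
  emit <- function(x, fname, rn = FALSE) {
    path <- file.path(out_dir, fname)
    if (rn) x <- data.frame(gene_id = rownames(x), as.data.frame(x),
                            check.names = FALSE)
    ok <- tryCatch({
      utils::write.table(x, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop_format("cannot write %s", path)
    manifest <<- rbind(manifest, data.frame(file = fname, n_rows = nrow(x)))
  }
  if (!is.null(tables$piano_table)) emit(tables$piano_table, "piano_table.tsv")
  if (!is.null(tables$category_counts))
    emit(tables$category_counts, "category_counts.tsv")
  if (!is.null(tables$enrichment)) emit(tables$enrichment, "enrichment.tsv")
  if (!is.null(tables$log2_matrix))
    emit(tables$log2_matrix, "log2_matrix.tsv", rn = TRUE)
  if (!is.null(tables$size_factors))
    emit(data.frame(sample_id = names(tables$size_factors),
                    size_factor = unname(tables$size_factors)),
         "size_factors.tsv")
  for (nm in names(tables$contrasts %||% list())) {
    emit(tables$contrasts[[nm]], sprintf("contrast_%s.tsv", nm))
  }
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
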