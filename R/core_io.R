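# Readers and writers for every on-disk artifact the pipeline touches.
# Matrices are plain numeric matrices with probe rownames and sample
# colnames (the limma convention); sample sheets and manifests are
# data.frames. Readers validate and flag; they never filter or impute.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_format <- function(msg) stop(errorCondition(msg, class = c("episig_format_error", "episig_error")))
abort_validation <- function(msg) stop(errorCondition(msg, class = c("episig_validation_error", "episig_error")))

read_tsv_matrix <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1L) abort_format(sprintf("%s: empty file '%s'", what, path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  ncol_expected <- length(header)
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) abort_format(sprintf("%s: duplicate sample ids in '%s'", what, path))
  body <- fields[-1L]
  if (length(body) == 0L) {
    m <- matrix(numeric(0), nrow = 0, ncol = length(sample_ids),
                dimnames = list(character(0), sample_ids))
    return(m)
  }
  lens <- lengths(body)
  if (any(lens != ncol_expected)) {
    abort_format(sprintf("%s: ragged row(s) %s in '%s' (expected %d fields)",
                         what, paste(head(which(lens != ncol_expected), 3), collapse = ","),
                         path, ncol_expected))
  }
  flat <- unlist(body, use.names = FALSE)
  idx <- matrix(flat, nrow = length(body), ncol = ncol_expected, byrow = TRUE)
  probe_ids <- idx[, 1L]
  if (anyDuplicated(probe_ids)) {
    abort_format(sprintf("%s: duplicate probe id '%s' in '%s'", what,
                         probe_ids[duplicated(probe_ids)][1L], path))
  }
  vals <- suppressWarnings(as.numeric(idx[, -1L, drop = FALSE]))
  raw <- idx[, -1L, drop = FALSE]
  bad <- is.na(vals) & !(raw %in% c("NA", "nan", "NaN", ""))
  if (any(bad)) {
    i <- which(bad)[1L]
    abort_format(sprintf("%s: non-numeric value '%s' in '%s'", what, raw[i], path))
  }
  m <- matrix(vals, nrow = length(probe_ids), ncol = length(sample_ids),
              dimnames = list(probe_ids, sample_ids))
  m
}

#' Read a beta-value matrix
#'
#' Reads a TSV with probe ids in the first column and sample ids in the
#' header into a probes x samples matrix of methylation beta fractions.
#' "NA" tokens become missing values; any non-missing value outside
#' \[0, 1\] is a validation error naming the offending cell.
#'
#' @param path Path to a tab-separated file. Lines starting with `#` are
#'   treated as comments and skipped.
#' @return A numeric matrix with probe rownames and sample colnames.
#' @export
read_beta_matrix <- function(path) {
  m <- read_tsv_matrix(path, "beta matrix")
  validate_beta_matrix(m)
  m
}

#' @rdname read_beta_matrix
#' @export
read_detection_p <- function(path) {
  m <- read_tsv_matrix(path, "detection-p matrix")
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_validation(sprintf("detection p %g out of [0,1] at probe '%s', sample '%s'",
                             m[bad[1, 1], bad[1, 2]], rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  }
  m
}

#' Validate a beta matrix in memory
#'
#' Checks the invariants every beta matrix must satisfy: numeric matrix,
#' unique probe and sample ids, all non-missing values in \[0, 1\].
#'
#' @param beta A numeric matrix (probes x samples).
#' @return The matrix, invisibly.
#' @export
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) abort_validation("beta matrix must be a numeric matrix")
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    abort_validation("beta matrix must carry probe rownames and sample colnames")
  if (anyDuplicated(rownames(beta))) abort_validation("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(beta))) abort_validation("duplicate sample ids in beta matrix")
  bad <- which(!is.na(beta) & (beta < 0 | beta > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_validation(sprintf("beta value %g out of [0,1] at probe '%s', sample '%s'",
                             beta[bad[1, 1], bad[1, 2]],
                             rownames(beta)[bad[1, 1]], colnames(beta)[bad[1, 2]]))
  }
  invisible(beta)
}

SHEET_COLUMNS <- c("sample_id", "group_label", "sex", "age", "batch", "array_type", "cohort_role")

#' Read a sample sheet
#'
#' Reads a CSV sample sheet with the mandatory columns `sample_id`,
#' `group_label`, `sex`, `age`, `batch`, `array_type`, `cohort_role`.
#' Extra columns are preserved untouched. Ages must be nonnegative and
#' sample ids unique.
#'
#' @param path Path to a comma-separated file with a header row.
#' @return A data.frame, one row per sample.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  missing_cols <- setdiff(SHEET_COLUMNS, names(df))
  if (length(missing_cols) > 0)
    abort_format(sprintf("sample sheet missing column(s): %s", paste(missing_cols, collapse = ", ")))
  validate_sample_sheet(df)
  df
}

#' @rdname read_sample_sheet
#' @param sheet A sample-sheet data.frame.
#' @export
validate_sample_sheet <- function(sheet) {
  missing_cols <- setdiff(SHEET_COLUMNS, names(sheet))
  if (length(missing_cols) > 0)
    abort_format(sprintf("sample sheet missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(sheet$sample_id))
    abort_validation(sprintf("duplicate sample_id '%s'", sheet$sample_id[duplicated(sheet$sample_id)][1L]))
  if (!is.numeric(sheet$age)) abort_validation("age column must be numeric")
  if (any(!is.na(sheet$age) & sheet$age < 0))
    abort_validation(sprintf("negative age for sample '%s'",
                             sheet$sample_id[which(sheet$age < 0)[1L]]))
  bad_role <- setdiff(unique(sheet$cohort_role), c("discovery", "validation", "pool"))
  if (length(bad_role) > 0)
    abort_validation(sprintf("unknown cohort_role '%s'", bad_role[1L]))
  invisible(sheet)
}

#' Read a probe manifest
#'
#' TSV with columns `probe_id`, `chrom`, `pos` (1-based position of the
#' interrogated CpG cytosine), `strand`, `snp_overlap`, `cross_reactive`.
#' Boolean columns accept 0/1 or true/false. The reader retains every
#' probe, including flagged and sex-chromosome ones: filtering is a later
#' pipeline stage.
#'
#' @param path Path to a tab-separated manifest.
#' @return A data.frame with logical flag columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("probe_id", "chrom", "pos", "strand", "snp_overlap", "cross_reactive")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    abort_format(sprintf("manifest missing column(s): %s", paste(missing_cols, collapse = ", ")))
  if (anyDuplicated(df$probe_id))
    abort_format(sprintf("duplicate probe id '%s' in manifest", df$probe_id[duplicated(df$probe_id)][1L]))
  if (any(df$pos < 1)) abort_validation("manifest pos must be >= 1")
  to_lgl <- function(x) {
    if (is.logical(x)) return(x)
    if (is.numeric(x)) return(x != 0)
    tolower(as.character(x)) %in% c("1", "true", "t", "yes")
  }
  df$snp_overlap <- to_lgl(df$snp_overlap)
  df$cross_reactive <- to_lgl(df$cross_reactive)
  df
}

#' Read genomic intervals (BED3+)
#'
#' Returns 0-based half-open intervals sorted within each chromosome.
#' Unnamed records get names `interval_<i>`.
#'
#' @param path Path to a BED file (tab-separated, no header).
#' @return A data.frame with columns chrom, start, end, name.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 3) abort_format("BED file needs at least 3 columns")
  out <- data.frame(chrom = as.character(df[[1]]),
                    start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]),
                    name = if (ncol(df) >= 4) as.character(df[[4]]) else paste0("interval_", seq_len(nrow(df))),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end))
    abort_validation(sprintf("interval with start >= end at line %d", which(out$start >= out$end)[1L]))
  out <- out[order(out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene models (BED12)
#'
#' Parses BED12 records (0-based half-open), validating that exon blocks
#' are ordered, non-overlapping and contained in the gene span, and that
#' the thick (CDS) region lies within the span.
#'
#' @param path Path to a BED12 file.
#' @return A data.frame with one row per transcript; exon block sizes and
#'   starts kept as comma-separated strings plus parsed list columns
#'   `exon_starts`/`exon_ends` (absolute, 0-based half-open).
#' @export
read_bed12 <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 12) abort_format("BED12 file needs 12 columns")
  parse_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",", fixed = TRUE)[[1]])
  n <- nrow(df)
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    start <- as.integer(df[i, 2]); end <- as.integer(df[i, 3])
    thick_start <- as.integer(df[i, 7]); thick_end <- as.integer(df[i, 8])
    n_blocks <- as.integer(df[i, 10])
    sizes <- parse_ints(as.character(df[i, 11]))
    rel_starts <- parse_ints(as.character(df[i, 12]))
    if (start >= end) abort_validation(sprintf("gene '%s': start >= end", df[i, 4]))
    if (length(sizes) != n_blocks || length(rel_starts) != n_blocks)
      abort_format(sprintf("gene '%s': block count mismatch", df[i, 4]))
    abs_starts <- start + rel_starts
    abs_ends <- abs_starts + sizes
    if (is.unsorted(abs_starts, strictly = TRUE) || any(abs_ends[-n_blocks] > abs_starts[-1]))
      abort_validation(sprintf("gene '%s': exon blocks overlap or are unordered", df[i, 4]))
    if (abs_starts[1] < start || abs_ends[n_blocks] > end)
      abort_validation(sprintf("gene '%s': exon blocks outside gene span", df[i, 4]))
    if (thick_start < start || thick_end > end || thick_start > thick_end)
      abort_validation(sprintf("gene '%s': CDS outside gene span", df[i, 4]))
    exon_starts[[i]] <- abs_starts
    exon_ends[[i]] <- abs_ends
  }
  out <- data.frame(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                    end = as.integer(df[[3]]), name = as.character(df[[4]]),
                    score = df[[5]], strand = as.character(df[[6]]),
                    thick_start = as.integer(df[[7]]), thick_end = as.integer(df[[8]]),
                    stringsAsFactors = FALSE)
  out$exon_starts <- exon_starts
  out$exon_ends <- exon_ends
  ord <- order(out$chrom, out$start, out$end)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a tabular artifact as TSV
#'
#' Deterministic column order (as given), floats at fixed precision, so
#' that write/read round-trips losslessly at that precision. An optional
#' header comment (e.g. a run's config hash) is written as `#`-prefixed
#' lines which all package readers skip.
#'
#' @param x A data.frame or matrix. Matrices are written with a leading id
#'   column holding rownames.
#' @param path Output path.
#' @param digits Significant digits for numeric columns (default 10).
#' @param id_col Name of the leading id column when `x` is a matrix.
#' @param comment Optional character vector of comment lines (without `#`).
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, digits = 10, id_col = "probe_id", comment = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  if (is.matrix(x)) {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    df <- cbind(stats::setNames(data.frame(rownames(x) %||% as.character(seq_len(nrow(x))),
                                           stringsAsFactors = FALSE), id_col), df)
  } else {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
  }
  fmt <- function(col) {
    if (is.numeric(col) && !is.integer(col)) {
      out <- formatC(col, digits = digits, format = "g")
      out[is.na(col)] <- "NA"
      trimws(out)
    } else as.character(col)
  }
  body <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) body <- matrix(body, nrow = 1L)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df) > 0) writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_table
#' @export
write_matrix <- function(x, path, digits = 10, id_col = "probe_id", comment = NULL) {
  stopifnot(is.matrix(x))
  write_table(x, path, digits = digits, id_col = id_col, comment = comment)
}

#' @rdname write_table
#' @param path Path to a TSV previously written by [write_table()].
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                    check.names = FALSE)
}
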