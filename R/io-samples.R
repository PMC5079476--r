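# Readers and writers for user-facing files: expression tables, BED peak
# files (plain or scored), and metadata tables. All text inputs may be
# gzip-compressed; gzfile() reads plain text transparently.

read_text_lines <- function(path) {
  if (!file.exists(path)) stop(data_error("file not found: ", path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# split one line on tabs if it contains any, else on commas
split_fields <- function(line, delim) strsplit(line, delim, fixed = TRUE)[[1L]]

is_skippable <- function(line) {
  grepl("^\\s*$", line) || grepl("^#", line) ||
    grepl("^(track|browser)([ \t]|$)", line)
}

#' Read a gene expression table
#'
#' Parses a processed expression file: delimited text with one gene per row
#' carrying a gene identifier and an abundance value (FPKM or TPM). The
#' delimiter (tab or comma) is auto-detected from the first data line.
#' Duplicate gene IDs (after normalization) are resolved by keeping the
#' maximum value, with a warning.
#'
#' @param path file path (optionally gzipped).
#' @param id_column,value_column column selectors: integer position, or
#'   column name when `has_header = TRUE`.
#' @param has_header logical; is the first non-comment line a header?
#' @param sample_name label for the sample; defaults to the file name
#'   without extension.
#' @return an [expression_sample()].
#' @export
read_expression_table <- function(path, id_column = 1L, value_column = 2L,
                                  has_header = FALSE, sample_name = NULL) {
  if (is.null(sample_name)) {
    sample_name <- sub("\\.(tsv|csv|txt)(\\.gz)?$", "", basename(path))
  }
  lines <- read_text_lines(path)
  keep <- !vapply(lines, is_skippable, logical(1L), USE.NAMES = FALSE)
  data_idx <- which(keep)
  if (length(data_idx) == 0L) stop(data_error("no usable rows in ", path))
  delim <- if (grepl("\t", lines[data_idx[1L]], fixed = TRUE)) "\t" else ","

  resolve_col <- function(sel, header) {
    if (is.numeric(sel)) return(as.integer(sel))
    if (is.null(header)) {
      stop(usage_error("column name '", sel, "' given but has_header = FALSE"))
    }
    j <- match(sel, header)
    if (is.na(j)) {
      stop(usage_error("column '", sel, "' not found; header has: ",
                       paste(header, collapse = ", ")))
    }
    j
  }

  header <- NULL
  if (has_header) {
    header <- split_fields(lines[data_idx[1L]], delim)
    data_idx <- data_idx[-1L]
    if (length(data_idx) == 0L) stop(data_error("no usable rows in ", path))
  }
  ic <- resolve_col(id_column, header)
  vc <- resolve_col(value_column, header)

  ids <- character(length(data_idx))
  vals <- numeric(length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    f <- split_fields(lines[i], delim)
    if (length(f) < max(ic, vc)) {
      stop(data_error(path, " line ", i, ": expected at least ", max(ic, vc),
                      " columns, found ", length(f)))
    }
    v <- suppressWarnings(as.numeric(f[vc]))
    if (is.na(v)) {
      stop(data_error(path, " line ", i, ": non-numeric value '", f[vc], "'"))
    }
    if (!is.finite(v) || v < 0) {
      stop(data_error(path, " line ", i, ": value must be finite and >= 0"))
    }
    ids[k] <- f[ic]
    vals[k] <- v
  }
  ids <- normalize_gene_id(ids)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning(sprintf("%s: %d duplicate gene ID(s) (e.g. %s); keeping max value",
                    path, length(dup), dup[1L]))
    vals <- vapply(split(vals, ids), max, numeric(1L))
    ids <- names(vals)
    names(vals) <- NULL
  }
  expression_sample(sample_name, ids, vals)
}

#' Write an expression table
#'
#' Two-column tab-separated output: gene ID and value. Inverse of
#' [read_expression_table()] with default columns.
#'
#' @param sample an [expression_sample()].
#' @param path output file path.
#' @export
write_expression_table <- function(sample, path) {
  stopifnot(inherits(sample, "ExpressionSample"))
  writeLines(sprintf("%s\t%.17g", sample$gene_id, sample$value), path)
  invisible(NULL)
}

#' Read a BED peak file
#'
#' Parses BED-format peak calls (>= 3 columns, 0-based half-open
#' coordinates, tab- or whitespace-separated). `track`, `browser` and `#`
#' lines are skipped. Coordinates are kept 0-based half-open; no
#' conversion is applied. With `scored = TRUE` a numeric score column
#' (BED column 5 by default) supplies CAGE-style expression values.
#'
#' @param path file path (optionally gzipped).
#' @param scored logical; read a score column?
#' @param score_column 1-based column index of the score (default 5).
#' @param sample_name label; defaults to the file name without extension.
#' @return a [peak_sample()] with intervals sorted by (chrom, start).
#' @export
read_peak_file <- function(path, scored = FALSE, score_column = 5L,
                           sample_name = NULL) {
  if (is.null(sample_name)) {
    sample_name <- sub("\\.(bed|txt)(\\.gz)?$", "", basename(path))
  }
  lines <- read_text_lines(path)
  data_idx <- which(!vapply(lines, is_skippable, logical(1L), USE.NAMES = FALSE))
  if (length(data_idx) == 0L) stop(data_error("no intervals in ", path))

  n <- length(data_idx)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  score <- if (scored) numeric(n) else NULL
  for (k in seq_len(n)) {
    i <- data_idx[k]
    f <- strsplit(lines[i], "[ \t]+")[[1L]]
    if (length(f) < 3L) {
      stop(data_error(path, " line ", i, ": BED needs >= 3 columns"))
    }
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e)) {
      stop(data_error(path, " line ", i, ": non-numeric coordinates"))
    }
    if (s < 0) stop(data_error(path, " line ", i, ": negative start"))
    if (s >= e) stop(data_error(path, " line ", i, ": start >= end"))
    chrom[k] <- f[1L]; start[k] <- s; end[k] <- e
    if (scored) {
      if (length(f) < score_column) {
        stop(data_error(path, " line ", i, ": score column ", score_column,
                        " absent (", length(f), " columns)"))
      }
      sc <- suppressWarnings(as.numeric(f[score_column]))
      if (is.na(sc)) {
        stop(data_error(path, " line ", i, ": non-numeric score '",
                        f[score_column], "'"))
      }
      score[k] <- sc
    }
  }
  iv <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (scored) iv$score <- score
  peak_sample(sample_name, iv, scored = scored)
}

#' Write a BED peak file
#'
#' Plain samples are written as BED3; scored samples as BED5 with a
#' placeholder name column. Inverse of [read_peak_file()].
#'
#' @param sample a [peak_sample()].
#' @param path output file path.
#' @export
write_peak_file <- function(sample, path) {
  stopifnot(inherits(sample, "PeakSample"))
  iv <- sample$intervals
  lines <- if (sample$scored) {
    sprintf("%s\t%d\t%d\tpeak%d\t%.17g", iv$chrom, as.integer(iv$start),
            as.integer(iv$end), seq_len(nrow(iv)), iv$score)
  } else {
    sprintf("%s\t%d\t%d", iv$chrom, as.integer(iv$start), as.integer(iv$end))
  }
  writeLines(lines, path)
  invisible(NULL)
}

#' Read an experiment metadata table
#'
#' Tab-separated table with a header; the first column is the experiment
#' identifier, remaining columns are free-form attributes (cell type,
#' factor, tissue, source link...). Used for sub-selecting compendium
#' experiments.
#'
#' @param path file path (optionally gzipped).
#' @return data.frame with first column `experiment_id`.
#' @export
read_metadata <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!vapply(lines, is_skippable, logical(1L), USE.NAMES = FALSE)]
  if (length(lines) == 0L) stop(data_error("empty metadata file: ", path))
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(lines) == 1L) stop(data_error("no records in metadata file: ", path))
  rows <- lapply(seq.int(2L, length(lines)), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    length(f) <- length(header)  # pad short rows with NA
    f
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- header
  names(df)[1L] <- "experiment_id"
  df[is.na(df)] <- ""
  if (anyDuplicated(df$experiment_id)) {
    dup <- unique(df$experiment_id[duplicated(df$experiment_id)])
    stop(data_error(path, ": duplicate experiment_id: ",
                    paste(dup, collapse = ", ")))
  }
  df
}

#' Write an experiment metadata table
#'
#' @param metadata data.frame as returned by [read_metadata()].
#' @param path output file path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
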