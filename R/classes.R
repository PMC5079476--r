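# Domain types: lightweight S3 containers with validating constructors.

#' Normalize a gene identifier
#'
#' Case-folds and strips a trailing numeric version suffix (e.g.
#' \code{"ENSG00000139618.14"} becomes \code{"ensg00000139618"}) so that
#' user files and compendia built from different annotation releases match.
#'
#' @param x character vector of gene identifiers.
#' @return character vector of normalized identifiers.
#' @export
normalize_gene_id <- function(x) {
  sub("\\.[0-9]+$", "", tolower(trimws(x)))
}

#' Expression sample
#'
#' One experiment's processed gene expression output: gene identifiers with
#' non-negative abundance values (FPKM or TPM). Gene identifiers are stored
#' normalized (see [normalize_gene_id()]) and must be unique.
#'
#' @param sample_name single character label.
#' @param gene_id character vector of gene identifiers (normalized on
#'   construction).
#' @param value numeric vector of non-negative finite abundances.
#' @return an object of class `ExpressionSample` with fields `sample_name`,
#'   `gene_id`, `value`.
#' @export
expression_sample <- function(sample_name, gene_id, value) {
  stopifnot(is.character(sample_name), length(sample_name) == 1L)
  gene_id <- normalize_gene_id(as.character(gene_id))
  value <- as.numeric(value)
  if (length(gene_id) != length(value)) {
    stop("gene_id and value must have the same length")
  }
  if (length(gene_id) == 0L) {
    stop(data_error("expression sample '", sample_name, "' has zero entries"))
  }
  if (anyDuplicated(gene_id)) {
    stop(data_error("duplicate gene IDs after normalization in sample '",
                    sample_name, "'"))
  }
  if (any(!is.finite(value)) || any(value < 0)) {
    stop(data_error("expression values must be finite and >= 0 in sample '",
                    sample_name, "'"))
  }
  structure(list(sample_name = sample_name, gene_id = gene_id, value = value),
            class = "ExpressionSample")
}

#' @export
print.ExpressionSample <- function(x, ...) {
  cat(sprintf("ExpressionSample '%s': %d genes, value range [%g, %g]\n",
              x$sample_name, length(x$gene_id), min(x$value), max(x$value)))
  invisible(x)
}

#' Peak sample
#'
#' One experiment's peak calls: genomic intervals in 0-based half-open
#' coordinates, optionally scored (CAGE expression values). Intervals are
#' sorted by (chrom, start, end) on construction.
#'
#' @param sample_name single character label.
#' @param intervals data.frame with columns `chrom`, `start`, `end` and,
#'   when `scored`, `score`. Coordinates are 0-based half-open.
#' @param scored logical; `TRUE` for CAGE-style scored peaks.
#' @return an object of class `PeakSample`.
#' @export
peak_sample <- function(sample_name, intervals, scored = FALSE) {
  stopifnot(is.character(sample_name), length(sample_name) == 1L,
            is.data.frame(intervals))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(intervals))) {
    stop("intervals must have columns chrom, start, end")
  }
  iv <- data.frame(
    chrom = as.character(intervals$chrom),
    start = as.numeric(intervals$start),
    end = as.numeric(intervals$end),
    stringsAsFactors = FALSE
  )
  if (scored) {
    if (!"score" %in% names(intervals)) {
      stop(data_error("scored peak sample '", sample_name,
                      "' is missing a score column"))
    }
    iv$score <- as.numeric(intervals$score)
    if (any(!is.finite(iv$score)) || any(iv$score < 0)) {
      stop(data_error("scores must be finite and >= 0 in sample '",
                      sample_name, "'"))
    }
  }
  if (nrow(iv) > 0L) {
    if (any(iv$chrom == "")) stop(data_error("empty chrom name in '", sample_name, "'"))
    if (any(iv$start < 0)) stop(data_error("negative start coordinate in '", sample_name, "'"))
    if (any(iv$start >= iv$end)) {
      stop(data_error("interval with start >= end in '", sample_name, "'"))
    }
    iv <- iv[order(iv$chrom, iv$start, iv$end), , drop = FALSE]
    rownames(iv) <- NULL
  }
  structure(list(sample_name = sample_name, intervals = iv, scored = scored),
            class = "PeakSample")
}

#' @export
print.PeakSample <- function(x, ...) {
  cat(sprintf("PeakSample '%s': %d intervals on %d chrom(s)%s\n",
              x$sample_name, nrow(x$intervals),
              length(unique(x$intervals$chrom)),
              if (x$scored) " (scored)" else ""))
  invisible(x)
}

#' Region universe
#'
#' The fixed, ordered, non-overlapping set of genomic regions forming the
#' feature space of a peak or CAGE compendium. Coordinates are 0-based
#' half-open.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`.
#' @return an object of class `RegionUniverse`.
#' @export
region_universe <- function(regions) {
  stopifnot(is.data.frame(regions))
  df <- data.frame(chrom = as.character(regions$chrom),
                   start = as.numeric(regions$start),
                   end = as.numeric(regions$end),
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(data_error("region universe is empty"))
  if (any(df$start < 0) || any(df$start >= df$end)) {
    stop(data_error("region universe has invalid coordinates"))
  }
  ord <- order(df$chrom, df$start, df$end)
  if (!identical(ord, seq_len(nrow(df)))) df <- df[ord, , drop = FALSE]
  # non-overlap within chrom: previous end must not exceed next start
  same <- df$chrom[-1L] == df$chrom[-nrow(df)]
  if (any(same & df$end[-nrow(df)] > df$start[-1L])) {
    stop(data_error("region universe contains overlapping regions"))
  }
  rownames(df) <- NULL
  structure(list(regions = df), class = "RegionUniverse")
}

#' @export
print.RegionUniverse <- function(x, ...) {
  cat(sprintf("RegionUniverse: %d regions on %d chrom(s), %g bp total\n",
              nrow(x$regions), length(unique(x$regions$chrom)),
              sum(x$regions$end - x$regions$start)))
  invisible(x)
}

# feature labels for region rows, "chrom:start-end" (0-based half-open)
region_labels <- function(universe) {
  r <- universe$regions
  sprintf("%s:%d-%d", r$chrom, as.integer(r$start), as.integer(r$end))
}

#' Compendium
#'
#' A feature x experiment matrix plus per-experiment metadata. Rows are
#' gene IDs (expression) or universe regions (peaks, CAGE); columns are
#' experiments. Peak matrices are binary (0/1); expression and CAGE
#' matrices hold log-scaled values, log(value + pseudocount).
#'
#' @param data_type one of `"expression"`, `"peaks"`, `"cage"`.
#' @param features character vector of gene IDs (expression) or a
#'   [region_universe()] (peaks/cage).
#' @param matrix numeric matrix, features x experiments, with experiment
#'   IDs as column names.
#' @param metadata data.frame; first column `experiment_id`, one row per
#'   matrix column, in column order.
#' @param transform list: `list(type = "binary")` for peaks, or
#'   `list(type = "log", base = <num>, pseudocount = <num>)`.
#' @return an object of class `Compendium`.
#' @export
compendium <- function(data_type, features, matrix, metadata, transform) {
  data_type <- match.arg(data_type, c("expression", "peaks", "cage"))
  if (data_type == "expression") {
    stopifnot(is.character(features))
    nfeat <- length(features)
    feat_labels <- features
  } else {
    stopifnot(inherits(features, "RegionUniverse"))
    nfeat <- nrow(features$regions)
    feat_labels <- region_labels(features)
  }
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (nrow(matrix) != nfeat) {
    stop(data_error("matrix has ", nrow(matrix), " rows but ", nfeat,
                    " features"))
  }
  stopifnot(is.data.frame(metadata), names(metadata)[1L] == "experiment_id")
  if (ncol(matrix) != nrow(metadata)) {
    stop(data_error("matrix has ", ncol(matrix), " columns but metadata has ",
                    nrow(metadata), " records"))
  }
  if (anyDuplicated(metadata$experiment_id)) {
    stop(data_error("duplicate experiment_id in metadata"))
  }
  colnames(matrix) <- as.character(metadata$experiment_id)
  rownames(matrix) <- feat_labels
  if (data_type == "peaks") {
    if (!identical(transform, list(type = "binary"))) {
      stop("peaks compendium requires transform = list(type = \"binary\")")
    }
    if (!all(matrix %in% c(0, 1))) {
      stop(data_error("peaks matrix must contain only 0/1"))
    }
  } else {
    stopifnot(identical(transform$type, "log"),
              is.numeric(transform$base), is.numeric(transform$pseudocount))
    if (transform$pseudocount < 1) {
      stop("pseudocount must be >= 1 so log-scaled values stay non-negative")
    }
    if (any(!is.finite(matrix)) || any(matrix < 0)) {
      stop(data_error("log-scaled matrix entries must be finite and >= 0"))
    }
  }
  rownames(metadata) <- NULL
  structure(list(data_type = data_type, features = features, matrix = matrix,
                 metadata = metadata, transform = transform),
            class = "Compendium")
}

#' @export
print.Compendium <- function(x, ...) {
  tr <- if (identical(x$transform$type, "binary")) "binary" else
    sprintf("log base %g, pseudocount %g", x$transform$base,
            x$transform$pseudocount)
  cat(sprintf("Compendium [%s]: %d features x %d experiments (%s)\n",
              x$data_type, nrow(x$matrix), ncol(x$matrix), tr))
  cat("metadata keys:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

n_experiments <- function(x) ncol(x$matrix)
n_features <- function(x) nrow(x$matrix)
experiment_ids <- function(x) colnames(x$matrix)

# apply a compendium's transform to raw non-negative values
apply_transform <- function(raw, transform) {
  if (identical(transform$type, "binary")) {
    return(as.numeric(raw != 0))
  }
  log(raw + transform$pseudocount, base = transform$base)
}

#' Projected sample
#'
#' A user sample aligned to a compendium's feature index: one more column,
#' exactly comparable to the reference experiments.
#'
#' @return `project_expression()`, `project_peaks()` and `project_cage()`
#'   return objects of this class with fields `sample_name`, `vector`
#'   (aligned to the compendium features, compendium transform applied) and
#'   `coverage` (a list of counts: `features_matched`, `features_filled`,
#'   `user_items`, `user_matched`, `user_unmatched`).
#' @name ProjectedSample
NULL

projected_sample <- function(sample_name, vector, coverage) {
  structure(list(sample_name = sample_name, vector = vector,
                 coverage = coverage),
            class = "ProjectedSample")
}

#' @export
print.ProjectedSample <- function(x, ...) {
  cv <- x$coverage
  cat(sprintf(paste0("ProjectedSample '%s': %d features ",
                     "(%d matched, %d filled as absent); %d/%d user items matched\n"),
              x$sample_name, length(x$vector), cv$features_matched,
              cv$features_filled, cv$user_matched, cv$user_items))
  invisible(x)
}

# condition helpers: data errors (malformed/contradictory input files) vs
# usage errors (bad flags/arguments); the CLI maps them to exit codes 2 and 1.
data_error <- function(...) {
  structure(class = c("seqcor_data_error", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1L)))
}

usage_error <- function(...) {
  structure(class = c("seqcor_usage_error", "error", "condition"),
            list(message = paste0(...), call = sys.call(-1L)))
}

# run code with a fixed seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
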