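# On-disk compendium format: a directory holding
#   manifest.json  format version, data type, transform
#   matrix.tsv     features x experiments, header = experiment IDs
#   features.tsv   gene_id column, or chrom/start/end for region universes
#   metadata.tsv   experiment metadata, first column experiment_id
# Doubles are written with %.17g so the round trip is bit-exact.

COMPENDIUM_FORMAT_VERSION <- 1L

#' Write a compendium to a directory
#'
#' @param x a [compendium()].
#' @param directory output directory (created if absent).
#' @seealso [read_compendium()] for the inverse; the round trip is
#'   bit-exact on matrix values.
#' @export
write_compendium <- function(x, directory) {
  stopifnot(inherits(x, "Compendium"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    format_version = COMPENDIUM_FORMAT_VERSION,
    data_type = x$data_type,
    transform = x$transform,
    n_features = n_features(x),
    n_experiments = n_experiments(x)
  )
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ids <- experiment_ids(x)
  con <- file(file.path(directory, "matrix.tsv"), "w")
  on.exit(close(con))
  writeLines(paste(ids, collapse = "\t"), con)
  body <- if (x$data_type == "peaks") {
    apply(x$matrix, 1L, function(r) paste(as.integer(r), collapse = "\t"))
  } else {
    apply(x$matrix, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  }
  writeLines(body, con)

  if (x$data_type == "expression") {
    writeLines(c("gene_id", x$features), file.path(directory, "features.tsv"))
  } else {
    r <- x$features$regions
    writeLines(c("chrom\tstart\tend",
                 sprintf("%s\t%d\t%d", r$chrom, as.integer(r$start),
                         as.integer(r$end))),
               file.path(directory, "features.tsv"))
  }
  write_metadata(x$metadata, file.path(directory, "metadata.tsv"))
  invisible(NULL)
}

#' Read a compendium from a directory
#'
#' Loads and cross-checks the manifest, matrix, feature index and metadata
#' (dimensions must agree across all three files).
#'
#' @param directory a directory written by [write_compendium()].
#' @return a [compendium()].
#' @export
read_compendium <- function(directory) {
  need <- file.path(directory, c("manifest.json", "matrix.tsv",
                                 "features.tsv", "metadata.tsv"))
  if (!dir.exists(directory) || !all(file.exists(need))) {
    stop(data_error(directory, " is not a compendium directory ",
                    "(missing manifest.json/matrix.tsv/features.tsv/metadata.tsv)"))
  }
  manifest <- jsonlite::read_json(need[1L], simplifyVector = TRUE)
  if (!identical(as.integer(manifest$format_version),
                 COMPENDIUM_FORMAT_VERSION)) {
    stop(data_error("unsupported compendium format version: ",
                    manifest$format_version))
  }
  data_type <- manifest$data_type
  transform <- manifest$transform

  mlines <- read_text_lines(need[2L])
  ids <- strsplit(mlines[1L], "\t", fixed = TRUE)[[1L]]
  nexp <- length(ids)
  body <- mlines[-1L]
  vals <- scan(text = body, what = double(), sep = "\t", quiet = TRUE)
  if (length(vals) != length(body) * nexp) {
    stop(data_error(need[2L], ": ragged matrix (", length(vals),
                    " values for ", length(body), " x ", nexp, ")"))
  }
  mat <- matrix(vals, nrow = length(body), ncol = nexp, byrow = TRUE)

  flines <- read_text_lines(need[3L])
  features <- if (data_type == "expression") {
    if (!identical(flines[1L], "gene_id")) {
      stop(data_error(need[3L], ": expected 'gene_id' header"))
    }
    flines[-1L]
  } else {
    parts <- strsplit(flines[-1L], "\t", fixed = TRUE)
    region_universe(data.frame(
      chrom = vapply(parts, `[`, "", 1L),
      start = as.numeric(vapply(parts, `[`, "", 2L)),
      end = as.numeric(vapply(parts, `[`, "", 3L)),
      stringsAsFactors = FALSE))
  }
  nfeat <- if (data_type == "expression") length(features) else
    nrow(features$regions)
  if (nrow(mat) != nfeat) {
    stop(data_error(directory, ": matrix has ", nrow(mat),
                    " rows but features.tsv lists ", nfeat))
  }
  metadata <- read_metadata(need[4L])
  if (nrow(metadata) != nexp) {
    stop(data_error(directory, ": matrix has ", nexp,
                    " columns but metadata.tsv has ", nrow(metadata), " records"))
  }
  if (!identical(as.character(metadata$experiment_id), ids)) {
    stop(data_error(directory,
                    ": metadata experiment order disagrees with matrix header"))
  }
  if (identical(manifest$n_features, NULL) ||
      as.integer(manifest$n_features) != nfeat ||
      as.integer(manifest$n_experiments) != nexp) {
    stop(data_error(directory, ": manifest dimensions disagree with files"))
  }
  tr <- if (data_type == "peaks") list(type = "binary") else
    list(type = "log", base = as.numeric(transform$base),
         pseudocount = as.numeric(transform$pseudocount))
  compendium(data_type, features, mat, metadata, tr)
}
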