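# Compendium construction: the three matrix kinds (log-scaled expression,
# binary peak presence over a merged region universe, log-scaled CAGE
# region expression) and metadata sub-selection. Interval arithmetic goes
# through GenomicRanges/IRanges; 0-based half-open coordinates are
# converted to 1-based closed only at the GRanges boundary.

# 0-based half-open data.frame -> GRanges (1-based closed)
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = sort(unique(df$chrom))),
    ranges = IRanges::IRanges(start = as.integer(df$start) + 1L,
                              end = as.integer(df$end)))
}

# overlapsAny without the seqlevel-mismatch chatter: user samples may
# legitimately sit on chromosomes absent from the universe (zero overlap)
overlaps_any <- function(query, subject) {
  withCallingHandlers(
    IRanges::overlapsAny(query, subject),
    warning = function(w) {
      if (grepl("sequence levels", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

universe_granges <- function(universe) as_granges(universe$regions)

#' Build a region universe from peak samples
#'
#' The universe is the union of all intervals with overlapping or
#' bookended intervals merged into single regions, sorted by
#' (chrom, start). It defines the row index of peak and CAGE compendia
#' and is frozen at build time: user samples are projected onto it, never
#' extend it.
#'
#' @param peak_samples list of [peak_sample()] objects.
#' @return a [region_universe()].
#' @export
build_region_universe <- function(peak_samples) {
  stopifnot(is.list(peak_samples), length(peak_samples) > 0L)
  ivs <- do.call(rbind, lapply(peak_samples, function(s) {
    stopifnot(inherits(s, "PeakSample"))
    s$intervals[, c("chrom", "start", "end"), drop = FALSE]
  }))
  if (nrow(ivs) == 0L) stop(data_error("no intervals in any peak sample"))
  gr <- GenomicRanges::reduce(GenomicRanges::sort(as_granges(ivs)))
  region_universe(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE))
}

#' Binarize a peak sample over a region universe
#'
#' Entry r is 1 iff at least one sample interval overlaps universe region
#' r by >= 1 bp (half-open semantics: overlap iff max(starts) <
#' min(ends)), else 0. An empty sample gives the all-zero vector.
#'
#' @param sample a [peak_sample()].
#' @param universe a [region_universe()].
#' @return integer vector of 0/1 over universe regions.
#' @export
binarize_peaks <- function(sample, universe) {
  stopifnot(inherits(sample, "PeakSample"),
            inherits(universe, "RegionUniverse"))
  n <- nrow(universe$regions)
  if (nrow(sample$intervals) == 0L) return(integer(n))
  as.integer(overlaps_any(universe_granges(universe),
                                  as_granges(sample$intervals)))
}

# order metadata rows to match samples; error on mismatch
match_metadata <- function(sample_names, metadata) {
  stopifnot(is.data.frame(metadata))
  idx <- match(sample_names, metadata$experiment_id)
  if (anyNA(idx)) {
    stop(data_error("metadata is missing records for sample(s): ",
                    paste(sample_names[is.na(idx)], collapse = ", ")))
  }
  metadata[idx, , drop = FALSE]
}

#' Build a binary peak compendium
#'
#' Builds the merged region universe from the samples, then binarizes each
#' sample over it; every column has at least one 1 because each sample's
#' own peaks are part of the universe.
#'
#' @param samples list of [peak_sample()] objects.
#' @param metadata data.frame with one record per sample, matched by
#'   `experiment_id` = sample name.
#' @return a [compendium()] with `data_type = "peaks"`.
#' @export
build_peak_compendium <- function(samples, metadata) {
  if (length(samples) == 0L) stop(data_error("no peak samples given"))
  names_ <- vapply(samples, function(s) s$sample_name, "")
  md <- match_metadata(names_, metadata)
  universe <- build_region_universe(samples)
  ugr <- universe_granges(universe)
  mat <- vapply(samples, function(s) {
    if (nrow(s$intervals) == 0L) {
      numeric(length(ugr))
    } else {
      as.numeric(overlaps_any(ugr, as_granges(s$intervals)))
    }
  }, numeric(length(ugr)))
  mat <- matrix(mat, nrow = length(ugr))
  compendium("peaks", universe, mat, md, list(type = "binary"))
}

resolve_log_base <- function(log_base) {
  if (is.character(log_base)) {
    if (log_base %in% c("e", "ln")) return(exp(1))
    log_base <- suppressWarnings(as.numeric(log_base))
  }
  if (!isTRUE(log_base %in% c(2, 10)) && !isTRUE(abs(log_base - exp(1)) < 1e-12)) {
    stop(usage_error("log base must be 2, 10 or e"))
  }
  log_base
}

#' Build a log-scaled expression compendium
#'
#' The feature list is the union of gene IDs across samples (after
#' normalization); genes missing from a sample are filled with raw 0
#' before the transform, so the feature space is identical for all
#' columns. Matrix entries are `log(value + pseudocount)` in the chosen
#' base.
#'
#' @param samples list of [expression_sample()] objects.
#' @param metadata data.frame, one record per sample (`experiment_id` =
#'   sample name).
#' @param pseudocount added before the log; >= 1 so entries stay
#'   non-negative (default 1).
#' @param log_base 2 (default), 10, or `"e"`.
#' @return a [compendium()] with `data_type = "expression"`.
#' @export
build_expression_compendium <- function(samples, metadata, pseudocount = 1,
                                        log_base = 2) {
  if (length(samples) == 0L) stop(data_error("no expression samples given"))
  log_base <- resolve_log_base(log_base)
  names_ <- vapply(samples, function(s) s$sample_name, "")
  md <- match_metadata(names_, metadata)
  genes <- sort(unique(unlist(lapply(samples, `[[`, "gene_id"))))
  if (length(genes) == 0L) stop(data_error("empty gene union"))
  raw <- matrix(0, nrow = length(genes), ncol = length(samples))
  for (j in seq_along(samples)) {
    idx <- match(samples[[j]]$gene_id, genes)
    raw[idx, j] <- samples[[j]]$value
  }
  tr <- list(type = "log", base = log_base, pseudocount = pseudocount)
  compendium("expression", genes, apply_transform(raw, tr), md, tr)
}

# per-region score sums of a scored sample over a universe
region_score_sums <- function(sample, universe) {
  ugr <- universe_granges(universe)
  out <- numeric(length(ugr))
  if (nrow(sample$intervals) == 0L) return(out)
  hits <- withCallingHandlers(
    GenomicRanges::findOverlaps(ugr, as_granges(sample$intervals)),
    warning = function(w) {
      if (grepl("sequence levels", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  if (length(hits) > 0L) {
    agg <- tapply(sample$intervals$score[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), sum)
    out[as.integer(names(agg))] <- as.numeric(agg)
  }
  out
}

#' Build a log-scaled CAGE compendium
#'
#' The region universe is merged from the samples' peaks; each matrix
#' entry (r, s) is `log(sum of scores of sample-s intervals overlapping
#' region r + pseudocount)`.
#'
#' @inheritParams build_expression_compendium
#' @param samples list of scored [peak_sample()] objects.
#' @return a [compendium()] with `data_type = "cage"`.
#' @export
build_cage_compendium <- function(samples, metadata, pseudocount = 1,
                                  log_base = 2) {
  if (length(samples) == 0L) stop(data_error("no CAGE samples given"))
  log_base <- resolve_log_base(log_base)
  unscored <- vapply(samples, function(s) !isTRUE(s$scored), logical(1L))
  if (any(unscored)) {
    stop(data_error("unscored sample(s) in CAGE build: ",
                    paste(vapply(samples[unscored], `[[`, "", "sample_name"),
                          collapse = ", ")))
  }
  names_ <- vapply(samples, function(s) s$sample_name, "")
  md <- match_metadata(names_, metadata)
  universe <- build_region_universe(samples)
  raw <- vapply(samples, region_score_sums, numeric(nrow(universe$regions)),
                universe = universe)
  raw <- matrix(raw, nrow = nrow(universe$regions))
  tr <- list(type = "log", base = log_base, pseudocount = pseudocount)
  compendium("cage", universe, apply_transform(raw, tr), md, tr)
}

#' Subset a compendium by metadata attributes
#'
#' Restricts columns to experiments matching every filter key; the feature
#' index and matrix values are untouched (no re-binarization, no universe
#' rebuild), so correlations computed before and after subsetting agree on
#' the shared experiments.
#'
#' @param x a [compendium()].
#' @param filter named list or named character vector; an experiment
#'   matches when, for every name, its metadata value is in the
#'   corresponding set (e.g. `list(factor = "ER")`, or
#'   `c(cell_type = "MCF7")`).
#' @return a [compendium()] with the matching columns.
#' @export
subset_compendium <- function(x, filter) {
  stopifnot(inherits(x, "Compendium"))
  filter <- as.list(filter)
  if (length(filter) == 0L || is.null(names(filter)) ||
      any(names(filter) == "")) {
    stop(usage_error("filter must be a named list of metadata key = value"))
  }
  bad <- setdiff(names(filter), names(x$metadata))
  if (length(bad) > 0L) {
    stop(usage_error("unknown metadata key(s): ", paste(bad, collapse = ", "),
                     "; valid keys: ", paste(names(x$metadata), collapse = ", ")))
  }
  keep <- rep(TRUE, n_experiments(x))
  for (k in names(filter)) {
    keep <- keep & (x$metadata[[k]] %in% filter[[k]])
  }
  if (!any(keep)) {
    stop(data_error("filter matches zero experiments"))
  }
  compendium(x$data_type, x$features,
             x$matrix[, keep, drop = FALSE],
             x$metadata[keep, , drop = FALSE],
             x$transform)
}
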