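# Pearson correlation of a projected user sample against every compendium
# experiment, and the full pairwise experiment x experiment matrix.
# Zero-variance vectors (e.g. an all-zero projected peak vector) have
# undefined correlation: reported as NA and sorted/ordered last, never
# silently turned into 0.

has_variance <- function(x) {
  isTRUE(stats::var(x) > 0)
}

#' Pearson product-moment correlation
#'
#' Standard Pearson r with explicit handling of the degenerate case: when
#' either vector has zero variance the coefficient is undefined and
#' `NA_real_` is returned (no NaN propagation). On binary 0/1 vectors this
#' equals the phi coefficient.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return r in `[-1, 1]`, or `NA_real_` when undefined.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) {
    stop(usage_error("length mismatch: ", length(x), " vs ", length(y)))
  }
  if (length(x) < 3L) {
    stop(usage_error("need vectors of length >= 3, got ", length(x)))
  }
  if (!has_variance(x) || !has_variance(y)) return(NA_real_)
  r <- stats::cor(x, y)
  min(1, max(-1, r))
}

#' Correlate a projected user sample against every experiment
#'
#' One Pearson r per compendium experiment, returned as a ranked table
#' (descending r, undefined entries last) with the experiment metadata
#' attributes joined onto each row.
#'
#' @param projected a `ProjectedSample` aligned to `compendium`.
#' @param compendium the [compendium()] it was projected onto.
#' @return a data.frame of class `CorrelationTable` with columns
#'   `experiment_id`, `r`, then the metadata attributes.
#' @export
correlate_user <- function(projected, compendium) {
  stopifnot(inherits(projected, "ProjectedSample"),
            inherits(compendium, "Compendium"))
  if (length(projected$vector) != n_features(compendium)) {
    stop(usage_error("projected vector length ", length(projected$vector),
                     " does not match compendium feature count ",
                     n_features(compendium)))
  }
  mat <- compendium$matrix
  r <- if (!has_variance(projected$vector)) {
    rep(NA_real_, ncol(mat))
  } else {
    colvar <- apply(mat, 2L, stats::var)
    out <- rep(NA_real_, ncol(mat))
    ok <- colvar > 0
    if (any(ok)) {
      out[ok] <- as.vector(stats::cor(projected$vector,
                                      mat[, ok, drop = FALSE]))
    }
    pmin(1, pmax(-1, out))
  }
  tab <- data.frame(experiment_id = experiment_ids(compendium), r = r,
                    stringsAsFactors = FALSE)
  extra <- compendium$metadata[, setdiff(names(compendium$metadata),
                                         "experiment_id"), drop = FALSE]
  tab <- cbind(tab, extra)
  tab <- tab[order(-tab$r, na.last = TRUE), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "sample_name") <- projected$sample_name
  class(tab) <- c("CorrelationTable", "data.frame")
  tab
}

#' Pairwise correlation matrix of a compendium
#'
#' All pairwise Pearson r between experiments, optionally with a
#' projected user sample appended as an additional row/column.
#' Zero-variance columns produce undefined (NA) entries and are excluded
#' from clustering later, placed last in the ordering.
#'
#' @param compendium a [compendium()] with >= 2 experiments.
#' @param extra optional `ProjectedSample` to append.
#' @return an object of class `CorrelationMatrix`: list with fields `ids`,
#'   `r` (symmetric matrix, unit diagonal), `undefined` (ids with zero
#'   variance), `user_id` (the appended sample's id or NULL), `ordering`
#'   (permutation of ids; identity until [cluster_order()]), `linkage`
#'   (NULL until clustered).
#' @export
pairwise_matrix <- function(compendium, extra = NULL) {
  stopifnot(inherits(compendium, "Compendium"))
  if (n_experiments(compendium) < 2L) {
    stop(usage_error("need >= 2 experiments, compendium has ",
                     n_experiments(compendium)))
  }
  mat <- compendium$matrix
  ids <- experiment_ids(compendium)
  user_id <- NULL
  if (!is.null(extra)) {
    stopifnot(inherits(extra, "ProjectedSample"))
    if (length(extra$vector) != nrow(mat)) {
      stop(usage_error("projected vector does not match compendium features"))
    }
    user_id <- extra$sample_name
    if (user_id %in% ids) user_id <- paste0(user_id, " (user)")
    mat <- cbind(mat, extra$vector)
    ids <- c(ids, user_id)
  }
  colnames(mat) <- ids
  colvar <- apply(mat, 2L, stats::var)
  undef <- colvar == 0
  r <- suppressWarnings(stats::cor(mat))
  r[undef, ] <- NA_real_
  r[, undef] <- NA_real_
  r[!undef, !undef] <- pmin(1, pmax(-1, r[!undef, !undef]))
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  structure(list(ids = ids, r = r, undefined = ids[undef], user_id = user_id,
                 ordering = seq_along(ids), linkage = NULL),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat(sprintf("CorrelationMatrix: %d experiments%s%s\n", length(x$ids),
              if (length(x$undefined)) sprintf(", %d undefined",
                                               length(x$undefined)) else "",
              if (is.null(x$linkage)) "" else
                sprintf(", clustered (%s linkage)", x$linkage$method)))
  invisible(x)
}

#' @export
print.CorrelationTable <- function(x, ...) {
  cat(sprintf("CorrelationTable for '%s': %d experiments\n",
              attr(x, "sample_name"), nrow(x)))
  print.data.frame(utils::head(x, 10L))
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}
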