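# Projection of a user sample onto a compendium's frozen feature space.
# The user sample becomes one more column: same feature order, same
# transform, directly comparable to every reference experiment.

#' Project an expression sample onto an expression compendium
#'
#' Matches user genes to the compendium's gene index by normalized ID.
#' User genes absent from the compendium are dropped (counted in the
#' coverage report); compendium genes absent from the user file get raw 0;
#' the compendium's log transform is then applied.
#'
#' @param sample an [expression_sample()].
#' @param compendium an expression [compendium()].
#' @return a `ProjectedSample` (see [ProjectedSample]).
#' @export
project_expression <- function(sample, compendium) {
  stopifnot(inherits(sample, "ExpressionSample"),
            inherits(compendium, "Compendium"))
  if (compendium$data_type != "expression") {
    stop(usage_error("compendium data_type is '", compendium$data_type,
                     "', need 'expression'"))
  }
  feats <- compendium$features
  idx <- match(feats, sample$gene_id)
  matched <- !is.na(idx)
  if (!any(matched)) {
    stop(data_error(
      "zero gene overlap between user file and compendium; user IDs look like [",
      paste(utils::head(sample$gene_id, 3L), collapse = ", "),
      "], compendium IDs look like [",
      paste(utils::head(feats, 3L), collapse = ", "), "]"))
  }
  raw <- numeric(length(feats))
  raw[matched] <- sample$value[idx[matched]]
  n_matched <- sum(matched)
  coverage <- list(
    features_matched = n_matched,
    features_filled = length(feats) - n_matched,
    user_items = length(sample$gene_id),
    user_matched = n_matched,
    user_unmatched = length(sample$gene_id) - n_matched
  )
  projected_sample(sample$sample_name,
                   apply_transform(raw, compendium$transform), coverage)
}

#' Project a peak sample onto a binary peak compendium
#'
#' Binarizes the user peaks over the compendium's frozen region universe
#' (user peaks never extend it). User peaks overlapping no universe region
#' are counted as unmatched; if none match at all the projection is the
#' all-zero vector and a warning (not an error) is raised — its
#' correlation is then undefined and reported as such downstream.
#'
#' @param sample a [peak_sample()].
#' @param compendium a peaks [compendium()].
#' @return a `ProjectedSample` with a 0/1 vector.
#' @export
project_peaks <- function(sample, compendium) {
  stopifnot(inherits(sample, "PeakSample"),
            inherits(compendium, "Compendium"))
  if (compendium$data_type != "peaks") {
    stop(usage_error("compendium data_type is '", compendium$data_type,
                     "', need 'peaks'"))
  }
  if (nrow(sample$intervals) == 0L) {
    stop(data_error("user peak sample '", sample$sample_name, "' is empty"))
  }
  universe <- compendium$features
  vec <- as.numeric(binarize_peaks(sample, universe))
  user_matched <- sum(overlaps_any(as_granges(sample$intervals),
                                           universe_granges(universe)))
  n_user <- nrow(sample$intervals)
  if (user_matched == 0L) {
    warning(sprintf("no user peak in '%s' overlaps any universe region; %s",
                    sample$sample_name,
                    "projection is all-zero and its correlation undefined"))
  }
  coverage <- list(
    features_matched = sum(vec != 0),
    features_filled = sum(vec == 0),
    user_items = n_user,
    user_matched = user_matched,
    user_unmatched = n_user - user_matched
  )
  projected_sample(sample$sample_name, vec, coverage)
}

#' Project a scored (CAGE) peak sample onto a CAGE compendium
#'
#' Sums user interval scores per universe region, then applies the
#' compendium's log transform; regions receiving no score get
#' `log(pseudocount)`.
#'
#' @param sample a scored [peak_sample()].
#' @param compendium a cage [compendium()].
#' @return a `ProjectedSample`.
#' @export
project_cage <- function(sample, compendium) {
  stopifnot(inherits(sample, "PeakSample"),
            inherits(compendium, "Compendium"))
  if (compendium$data_type != "cage") {
    stop(usage_error("compendium data_type is '", compendium$data_type,
                     "', need 'cage'"))
  }
  if (!isTRUE(sample$scored)) {
    stop(data_error("CAGE projection requires a scored sample; '",
                    sample$sample_name, "' has no scores"))
  }
  universe <- compendium$features
  raw <- region_score_sums(sample, universe)
  user_matched <- if (nrow(sample$intervals) > 0L) {
    sum(overlaps_any(as_granges(sample$intervals),
                             universe_granges(universe)))
  } else 0L
  n_user <- nrow(sample$intervals)
  coverage <- list(
    features_matched = sum(raw != 0),
    features_filled = sum(raw == 0),
    user_items = n_user,
    user_matched = user_matched,
    user_unmatched = n_user - user_matched
  )
  projected_sample(sample$sample_name,
                   apply_transform(raw, compendium$transform), coverage)
}
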