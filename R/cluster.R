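# Agglomerative hierarchical clustering of the correlation matrix on the
# correlation distance d = 1 - r, with a fixed deterministic tie-break so
# outputs are bit-reproducible across runs and platforms: among equally
# close pairs, merge the one whose clusters contain the lowest original
# indices. Implemented directly (Lance-Williams updates) because that
# tie-break and the leaf-order convention are part of the contract;
# "ward" follows the squared-distance recursion (Ward on d itself, as
# hclust's ward.D2 does).

LINKAGE_METHODS <- c("complete", "average", "single", "ward")

# core agglomeration on a distance matrix; returns merge/height (hclust
# convention) and the deterministic leaf order
agglomerate <- function(D, method) {
  n <- nrow(D)
  stopifnot(n >= 2L)
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  minorig <- seq_len(n)              # smallest original index per cluster
  members <- lapply(seq_len(n), identity)  # leaves in display order
  clustid <- -seq_len(n)             # hclust id: -obs or +step
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  d <- D
  diag(d) <- Inf

  for (step in seq_len(n - 1L)) {
    dm <- d
    dm[!active, ] <- Inf
    dm[, !active] <- Inf
    m <- min(dm)
    cand <- which(dm == m, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    lo <- pmin(minorig[cand[, 1L]], minorig[cand[, 2L]])
    hi <- pmax(minorig[cand[, 1L]], minorig[cand[, 2L]])
    pick <- order(lo, hi)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    a <- clustid[i]; b <- clustid[j]
    merge[step, ] <- sort(c(a, b))  # singletons (negative ids) sort first
    height[step] <- m

    # display order: subtree holding the lowest original index first
    members[[i]] <- if (minorig[i] <= minorig[j]) {
      c(members[[i]], members[[j]])
    } else {
      c(members[[j]], members[[i]])
    }

    # Lance-Williams update into slot i
    ks <- which(active); ks <- ks[ks != i & ks != j]
    if (length(ks) > 0L) {
      dik <- d[i, ks]; djk <- d[j, ks]
      dnew <- switch(method,
        complete = pmax(dik, djk),
        single = pmin(dik, djk),
        average = (size[i] * dik + size[j] * djk) / (size[i] + size[j]),
        ward = sqrt(((size[i] + size[ks]) * dik^2 +
                     (size[j] + size[ks]) * djk^2 -
                     size[ks] * m^2) / (size[i] + size[j] + size[ks]))
      )
      d[i, ks] <- dnew
      d[ks, i] <- dnew
    }
    active[j] <- FALSE
    size[i] <- size[i] + size[j]
    minorig[i] <- min(minorig[i], minorig[j])
    clustid[i] <- step
  }
  list(merge = merge, height = height, order = members[[which(active)]])
}

#' Cluster a correlation matrix and set its display order
#'
#' Agglomerative hierarchical clustering on the correlation distance
#' `d = 1 - r` with a selectable linkage. Experiments with undefined
#' correlations (zero variance) are excluded from clustering and appended
#' at the end of the ordering. Ties are broken deterministically: the
#' candidate pair containing the lowest original indices merges first, and
#' in the leaf order the subtree holding the lowest original index comes
#' first.
#'
#' @param cm a `CorrelationMatrix` from [pairwise_matrix()].
#' @param method `"complete"` (default), `"average"`, `"single"` or
#'   `"ward"`.
#' @return the `CorrelationMatrix` with `ordering` set to the dendrogram
#'   leaf order (undefined experiments last) and `linkage` holding an
#'   `hclust`-compatible tree (fields `merge`, `height`, `order`,
#'   `labels`, `method`) plus the excluded ids.
#' @export
cluster_order <- function(cm, method = c("complete", "average", "single",
                                         "ward")) {
  stopifnot(inherits(cm, "CorrelationMatrix"))
  if (length(method) == 1L && !method %in% LINKAGE_METHODS) {
    stop(usage_error("unknown clustering method '", method, "'; choose from: ",
                     paste(LINKAGE_METHODS, collapse = ", ")))
  }
  method <- match.arg(method)
  def <- which(!cm$ids %in% cm$undefined)
  undef <- which(cm$ids %in% cm$undefined)
  if (length(def) < 2L) {
    cm$ordering <- c(def, undef)
    cm$linkage <- list(hclust = NULL, method = method,
                       excluded = cm$ids[undef])
    return(cm)
  }
  D <- 1 - cm$r[def, def, drop = FALSE]
  ag <- agglomerate(D, method)
  hc <- structure(list(merge = ag$merge, height = ag$height,
                       order = ag$order, labels = cm$ids[def],
                       method = method, dist.method = "1 - pearson"),
                  class = "hclust")
  cm$ordering <- c(def[ag$order], undef)
  cm$linkage <- list(hclust = hc, method = method, excluded = cm$ids[undef])
  cm
}
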