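# Independent brute-force oracles. These deliberately share no code with
# the package: interval logic is written as explicit loops over 0-based
# half-open tuples, correlation as the textbook two-pass formula, and
# clustering as a naive agglomerative that recomputes inter-cluster
# distances from the original matrix at every step.

# half-open overlap of two intervals on the same chromosome
iv_overlap <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 && max(s1, s2) < min(e1, e2)
}

# O(n*m) all-pairs binarization oracle
oracle_binarize <- function(sample_df, regions_df) {
  out <- integer(nrow(regions_df))
  for (i in seq_len(nrow(regions_df))) {
    for (j in seq_len(nrow(sample_df))) {
      if (iv_overlap(regions_df$chrom[i], regions_df$start[i],
                     regions_df$end[i], sample_df$chrom[j],
                     sample_df$start[j], sample_df$end[j])) {
        out[i] <- 1L
        break
      }
    }
  }
  out
}

# O(n^2) fixpoint merge oracle (overlapping or bookended intervals fuse)
oracle_merge <- function(df) {
  regs <- data.frame(chrom = as.character(df$chrom),
                     start = as.numeric(df$start),
                     end = as.numeric(df$end), stringsAsFactors = FALSE)
  repeat {
    n <- nrow(regs)
    merged <- FALSE
    for (i in seq_len(max(0L, n - 1L))) {
      for (j in seq.int(i + 1L, n)) {
        if (regs$chrom[i] == regs$chrom[j] &&
            max(regs$start[i], regs$start[j]) <=
              min(regs$end[i], regs$end[j])) {
          regs$start[i] <- min(regs$start[i], regs$start[j])
          regs$end[i] <- max(regs$end[i], regs$end[j])
          regs <- regs[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  regs <- regs[order(regs$chrom, regs$start), , drop = FALSE]
  rownames(regs) <- NULL
  regs
}

# per-base boolean coverage of a set of 0-based half-open intervals on a
# small genome model (list of chrom lengths)
oracle_coverage <- function(df, genome) {
  cov <- lapply(seq_len(nrow(genome)), function(i) logical(genome$length[i]))
  names(cov) <- genome$chrom
  for (j in seq_len(nrow(df))) {
    c <- df$chrom[j]
    cov[[c]][seq.int(df$start[j] + 1L, df$end[j])] <- TRUE
  }
  cov
}

# textbook two-pass Pearson correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# naive agglomerative clustering oracle: recomputes every inter-cluster
# distance from the original matrix each step (complete/single/average);
# ward follows the squared-distance recursion with freshly rebuilt
# matrices. Tie-break and leaf-order convention as documented by
# cluster_order(): lowest original indices merge first, subtree holding
# the lowest original index drawn first.
oracle_cluster_order <- function(D, method) {
  members <- lapply(seq_len(nrow(D)), identity)
  mins <- seq_len(nrow(D))
  sizes <- rep(1, nrow(D))
  cd <- D
  heights <- numeric(0)
  while (length(members) > 1L) {
    m <- length(members)
    best_d <- Inf; best_lo <- Inf; best_hi <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        dij <- if (method == "ward") cd[i, j] else {
          cross <- D[members[[i]], members[[j]], drop = FALSE]
          switch(method, complete = max(cross), single = min(cross),
                 average = mean(cross))
        }
        lo <- min(mins[i], mins[j]); hi <- max(mins[i], mins[j])
        if (dij < best_d ||
            (dij == best_d && (lo < best_lo ||
                               (lo == best_lo && hi < best_hi)))) {
          best_d <- dij; best_lo <- lo; best_hi <- hi; bi <- i; bj <- j
        }
      }
    }
    keep <- setdiff(seq_len(m), c(bi, bj))
    if (method == "ward") {
      newd <- vapply(keep, function(k) {
        sqrt(((sizes[bi] + sizes[k]) * cd[bi, k]^2 +
              (sizes[bj] + sizes[k]) * cd[bj, k]^2 -
              sizes[k] * cd[bi, bj]^2) /
             (sizes[bi] + sizes[bj] + sizes[k]))
      }, numeric(1L))
      cd <- rbind(cbind(cd[keep, keep, drop = FALSE], newd),
                  c(newd, 0))
    }
    heights <- c(heights, best_d)
    newm <- if (mins[bi] <= mins[bj]) c(members[[bi]], members[[bj]])
            else c(members[[bj]], members[[bi]])
    members <- c(members[keep], list(newm))
    mins <- c(mins[keep], min(mins[bi], mins[bj]))
    sizes <- c(sizes[keep], sizes[bi] + sizes[bj])
  }
  list(order = members[[1L]], heights = heights)
}

# random interval set on a genome model
rand_intervals <- function(n, genome, max_len = 500L) {
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- vapply(seq_len(n), function(k) {
    sample.int(genome$length[ci[k]] - len[k], 1L) - 1L
  }, numeric(1L))
  data.frame(chrom = genome$chrom[ci], start = start, end = start + len,
             stringsAsFactors = FALSE)
}

small_genome <- function(chrom_len = 1e7, n_chrom = 3L) {
  data.frame(chrom = paste0("chr", seq_len(n_chrom)),
             length = rep(chrom_len, n_chrom), stringsAsFactors = FALSE)
}

# are all groups contiguous in the given ordering of ids?
groups_contiguous <- function(ids_in_order, truth) {
  g <- truth[ids_in_order]
  all(vapply(unique(g), function(gg) {
    pos <- which(g == gg)
    max(pos) - min(pos) + 1L == length(pos)
  }, logical(1L)))
}
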