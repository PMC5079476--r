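# Synthetic compendia with planted correlation structure. Group structure
# is planted through a shared-latent-factor model: experiment e in group g
# draws, per feature,
#   x_e = sqrt(rho_out) * z_global + sqrt(rho_in - rho_out) * z_g
#         + sqrt(1 - rho_in) * eps_e
# so that cor(x_e, x_f) = rho_in within a group and rho_out across groups
# in expectation, with closed-form control. Expression/CAGE values are
# 2^(log_mean + log_sd * x) (FPKM-like, strictly positive); peak samples
# threshold the latent at qnorm(1 - density), with the latent correlation
# inflated (tetrachoric inversion) so the realized phi on the binary
# vectors lands on the design targets.

#' Synthetic compendium design
#'
#' Parameters of the planted-structure generators. Defaults emulate a
#' small reference compendium: 5 biological groups of 4 experiments over
#' 2000 features, strong within-group correlation (0.8) and weak
#' background correlation (0.1), on a 3-chromosome 10 Mb genome model.
#'
#' @param n_features number of genes (expression) or master regions
#'   (peaks/CAGE).
#' @param n_groups,per_group number of planted groups and experiments per
#'   group.
#' @param rho_in,rho_out target within-/between-group Pearson correlation
#'   (phi for binary peak matrices); `0 <= rho_out < rho_in <= 1`.
#' @param log_mean,log_sd location and scale of log2 expression values.
#' @param peak_density fraction of master regions carried by each peak
#'   sample (default 0.5, where the tetrachoric inversion is exact).
#' @param peak_width width of master regions in bp.
#' @param genome data.frame with columns `chrom`, `length`.
#' @param seed integer seed fixing all randomness end-to-end.
#' @return an object of class `SyntheticDesign`.
#' @export
synthetic_design <- function(n_features = 2000L, n_groups = 5L,
                             per_group = 4L, rho_in = 0.8, rho_out = 0.1,
                             log_mean = 5, log_sd = 2, peak_density = 0.5,
                             peak_width = 200L,
                             genome = data.frame(
                               chrom = c("chr1", "chr2", "chr3"),
                               length = rep(1e7, 3L)),
                             seed = 1L) {
  if (!(rho_out >= 0 && rho_out < rho_in && rho_in <= 1)) {
    stop(usage_error("need 0 <= rho_out < rho_in <= 1, got rho_in = ",
                     rho_in, ", rho_out = ", rho_out))
  }
  if (n_features < 1L || n_groups < 1L || per_group < 1L) {
    stop(usage_error("all counts must be positive"))
  }
  if (peak_density <= 0 || peak_density >= 1) {
    stop(usage_error("peak_density must be in (0, 1)"))
  }
  structure(list(n_features = as.integer(n_features),
                 n_groups = as.integer(n_groups),
                 per_group = as.integer(per_group),
                 rho_in = rho_in, rho_out = rho_out,
                 log_mean = log_mean, log_sd = log_sd,
                 peak_density = peak_density,
                 peak_width = as.integer(peak_width),
                 genome = genome, seed = as.integer(seed)),
            class = "SyntheticDesign")
}

# latent matrix: features x (experiments [+ users]); group g gets columns
# in blocks. Column marginals are standard normal.
latent_matrix <- function(design, per_group_total, rho_in, rho_out) {
  nf <- design$n_features
  G <- design$n_groups
  z_global <- stats::rnorm(nf)
  x <- matrix(0, nf, G * per_group_total)
  for (g in seq_len(G)) {
    z_g <- stats::rnorm(nf)
    for (k in seq_len(per_group_total)) {
      eps <- if (rho_in < 1) stats::rnorm(nf) else numeric(nf)
      x[, (g - 1L) * per_group_total + k] <-
        sqrt(rho_out) * z_global + sqrt(rho_in - rho_out) * z_g +
        sqrt(1 - rho_in) * eps
    }
  }
  x
}

synth_metadata <- function(design, ids, groups) {
  data.frame(experiment_id = ids,
             group = groups,
             source = "synthetic",
             stringsAsFactors = FALSE)
}

#' Generate a synthetic expression compendium
#'
#' Returns raw [expression_sample()]s (FPKM-like values), metadata whose
#' `group` attribute is the planted truth, and optionally held-out user
#' samples drawn from the same group latents.
#'
#' @param design a [synthetic_design()].
#' @param n_user_per_group extra samples per group returned separately as
#'   user samples (default 0).
#' @return list with `samples`, `metadata`, `truth` (named group vector),
#'   and `user_samples` / `user_truth` when requested.
#' @export
synth_expression_compendium <- function(design, n_user_per_group = 0L) {
  stopifnot(inherits(design, "SyntheticDesign"))
  with_seed(design$seed, {
    total <- design$per_group + n_user_per_group
    x <- latent_matrix(design, total, design$rho_in, design$rho_out)
    genes <- sprintf("gene%05d", seq_len(design$n_features))
    vals <- 2^(design$log_mean + design$log_sd * x)

    make_sample <- function(col, name) expression_sample(name, genes, vals[, col])
    samples <- list(); users <- list()
    ids <- character(0); groups <- character(0)
    user_truth <- character(0)
    for (g in seq_len(design$n_groups)) {
      for (k in seq_len(total)) {
        col <- (g - 1L) * total + k
        if (k <= design$per_group) {
          name <- sprintf("grp%02d_rep%02d", g, k)
          samples[[length(samples) + 1L]] <- make_sample(col, name)
          ids <- c(ids, name); groups <- c(groups, sprintf("group%02d", g))
        } else {
          name <- sprintf("user_grp%02d_%02d", g, k - design$per_group)
          users[[length(users) + 1L]] <- make_sample(col, name)
          user_truth <- c(user_truth, sprintf("group%02d", g))
          names(user_truth)[length(user_truth)] <- name
        }
      }
    }
    truth <- stats::setNames(groups, ids)
    out <- list(samples = samples, metadata = synth_metadata(design, ids, groups),
                truth = truth)
    if (n_user_per_group > 0L) {
      out$user_samples <- users
      out$user_truth <- user_truth
    }
    out
  })
}

# master regions: n_features non-overlapping fixed-width regions spread
# over the genome model proportionally to chromosome length, jittered
# within disjoint slots so they never overlap
master_regions <- function(design) {
  gl <- design$genome
  w <- design$peak_width
  k <- pmax(1L, round(design$n_features * gl$length / sum(gl$length)))
  # adjust rounding drift on the largest chromosome
  k[which.max(k)] <- k[which.max(k)] + design$n_features - sum(k)
  regs <- do.call(rbind, lapply(seq_len(nrow(gl)), function(i) {
    spacing <- floor(gl$length[i] / k[i])
    if (spacing <= w) stop(usage_error("genome too small for ", k[i],
                                       " regions of width ", w))
    jitter <- sample.int(spacing - w, k[i], replace = TRUE) - 1L
    start <- (seq_len(k[i]) - 1L) * spacing + jitter
    data.frame(chrom = gl$chrom[i], start = start, end = start + w,
               stringsAsFactors = FALSE)
  }))
  regs
}

# invert phi -> latent tetrachoric correlation for equal-margin
# dichotomisation at threshold tau = qnorm(1 - density); exact closed form
# at density 0.5, numeric inversion otherwise
phi_to_latent <- function(phi, density) {
  if (phi < 0 || phi >= 1) {
    stop(usage_error("phi target must be in [0, 1), got ", phi))
  }
  if (phi == 0) return(0)
  if (abs(density - 0.5) < 1e-12) return(sin(pi * phi / 2))
  tau <- stats::qnorm(1 - density)
  p <- 1 - stats::pnorm(tau)
  phi_of <- function(rho) {
    p11 <- stats::integrate(function(z) {
      stats::dnorm(z) * stats::pnorm((rho * z - tau) / sqrt(1 - rho^2))
    }, tau, Inf, rel.tol = 1e-10)$value
    (p11 - p^2) / (p * (1 - p))
  }
  stats::uniroot(function(rho) phi_of(rho) - phi,
                 interval = c(1e-9, 1 - 1e-9), tol = 1e-9)$root
}

#' Generate a synthetic peak compendium
#'
#' Draws a master set of non-overlapping regions on the genome model; each
#' sample keeps the regions where its latent factor exceeds the density
#' threshold, so the binarized matrix has within-/between-group phi close
#' to the design's `rho_in`/`rho_out`.
#'
#' @inheritParams synth_expression_compendium
#' @param scored generate CAGE-style scored samples: every sample carries
#'   all master regions with FPKM-like scores from the expression latent
#'   model instead of thresholded presence.
#' @return list with `samples` (peak samples), `metadata`, `truth`, the
#'   master `regions`, and user samples when requested.
#' @export
synth_peak_compendium <- function(design, n_user_per_group = 0L,
                                  scored = FALSE) {
  stopifnot(inherits(design, "SyntheticDesign"))
  with_seed(design$seed, {
    regs <- master_regions(design)
    total <- design$per_group + n_user_per_group
    if (scored) {
      x <- latent_matrix(design, total, design$rho_in, design$rho_out)
      vals <- 2^(design$log_mean + design$log_sd * x)
      make_sample <- function(col, name) {
        iv <- regs
        iv$score <- vals[, col]
        peak_sample(name, iv, scored = TRUE)
      }
    } else {
      rin <- if (design$rho_in >= 1) 1 else
        phi_to_latent(design$rho_in, design$peak_density)
      rout <- phi_to_latent(design$rho_out, design$peak_density)
      if (rout >= rin && rin < 1) {
        stop(usage_error("infeasible design: latent rho_out >= rho_in"))
      }
      x <- latent_matrix(design, total, rin, rout)
      tau <- stats::qnorm(1 - design$peak_density)
      make_sample <- function(col, name) {
        keep <- x[, col] > tau
        if (!any(keep)) stop(data_error("synthetic sample '", name,
                                        "' has zero peaks"))
        peak_sample(name, regs[keep, , drop = FALSE], scored = FALSE)
      }
    }
    samples <- list(); users <- list()
    ids <- character(0); groups <- character(0); user_truth <- character(0)
    for (g in seq_len(design$n_groups)) {
      for (k in seq_len(total)) {
        col <- (g - 1L) * total + k
        if (k <= design$per_group) {
          name <- sprintf("grp%02d_rep%02d", g, k)
          samples[[length(samples) + 1L]] <- make_sample(col, name)
          ids <- c(ids, name); groups <- c(groups, sprintf("group%02d", g))
        } else {
          name <- sprintf("user_grp%02d_%02d", g, k - design$per_group)
          users[[length(users) + 1L]] <- make_sample(col, name)
          user_truth <- c(user_truth, sprintf("group%02d", g))
          names(user_truth)[length(user_truth)] <- name
        }
      }
    }
    out <- list(samples = samples,
                metadata = synth_metadata(design, ids, groups),
                truth = stats::setNames(groups, ids),
                regions = regs)
    if (n_user_per_group > 0L) {
      out$user_samples <- users
      out$user_truth <- user_truth
    }
    out
  })
}

#' Generate a synthetic CAGE compendium
#'
#' Convenience wrapper: [synth_peak_compendium()] with `scored = TRUE`.
#'
#' @inheritParams synth_expression_compendium
#' @export
synth_cage_compendium <- function(design, n_user_per_group = 0L) {
  synth_peak_compendium(design, n_user_per_group, scored = TRUE)
}

#' Perturb a sample
#'
#' Produces a degraded copy for quality-control scenarios: at intensity 0
#' the sample is returned unchanged; at intensity 1 expression values are
#' fully permuted across genes (peaks: all intervals relocated to random
#' positions); the expected correlation with the original decreases
#' monotonically as intensity rises.
#'
#' @param sample an [expression_sample()] or [peak_sample()].
#' @param intensity fraction in `[0, 1]` of entries disturbed.
#' @param seed integer seed; the same seed reproduces the perturbation.
#' @param genome genome model (data.frame `chrom`, `length`) used to
#'   relocate peaks; defaults to the [synthetic_design()] default genome.
#' @return a sample of the same class.
#' @export
perturb_sample <- function(sample, intensity, seed = 1L,
                           genome = data.frame(
                             chrom = c("chr1", "chr2", "chr3"),
                             length = rep(1e7, 3L))) {
  if (!is.numeric(intensity) || intensity < 0 || intensity > 1) {
    stop(usage_error("intensity must be in [0, 1]"))
  }
  if (intensity == 0) return(sample)
  with_seed(seed, {
    if (inherits(sample, "ExpressionSample")) {
      n <- length(sample$value)
      m <- round(intensity * n)
      if (m >= 2L) {
        pick <- sample.int(n, m)
        v <- sample$value
        v[pick] <- v[pick][sample.int(m)]
        return(expression_sample(sample$sample_name, sample$gene_id, v))
      }
      return(sample)
    }
    if (inherits(sample, "PeakSample")) {
      iv <- sample$intervals
      n <- nrow(iv)
      m <- round(intensity * n)
      if (m >= 1L) {
        pick <- sample.int(n, m)
        w <- iv$end[pick] - iv$start[pick]
        ci <- sample.int(nrow(genome), m, replace = TRUE,
                         prob = genome$length)
        max_start <- genome$length[ci] - w
        new_start <- floor(stats::runif(m, 0, max_start))
        iv$chrom[pick] <- genome$chrom[ci]
        iv$start[pick] <- new_start
        iv$end[pick] <- new_start + w
      }
      return(peak_sample(sample$sample_name, iv, scored = sample$scored))
    }
    stop(usage_error("perturb_sample expects an ExpressionSample or PeakSample"))
  })
}
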