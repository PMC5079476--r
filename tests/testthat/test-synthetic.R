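test_that("design validation rejects contradictory correlation targets", {
  expect_error(synthetic_design(rho_in = 0.5, rho_out = 0.6),
               class = "seqcor_usage_error")
  expect_error(synthetic_design(rho_in = 1.2), class = "seqcor_usage_error")
  expect_error(synthetic_design(n_groups = 0), class = "seqcor_usage_error")
  expect_error(synthetic_design(peak_density = 0), class = "seqcor_usage_error")
})

test_that("the zero-noise limit produces identical group members", {
  d <- synthetic_design(n_features = 100, n_groups = 2, per_group = 3,
                        rho_in = 1, rho_out = 0.1, seed = 2)
  g <- synth_expression_compendium(d)
  expect_identical(g$samples[[1]]$value, g$samples[[2]]$value)
  expect_identical(g$samples[[1]]$value, g$samples[[3]]$value)
  expect_false(identical(g$samples[[1]]$value, g$samples[[4]]$value))

  gp <- synth_peak_compendium(d)
  expect_identical(gp$samples[[1]]$intervals, gp$samples[[2]]$intervals)
})

test_that("the same seed reproduces everything; different seeds differ", {
  d1 <- synthetic_design(n_features = 80, n_groups = 2, per_group = 2,
                         seed = 5)
  d2 <- synthetic_design(n_features = 80, n_groups = 2, per_group = 2,
                         seed = 6)
  a <- synth_expression_compendium(d1)
  b <- synth_expression_compendium(d1)
  c <- synth_expression_compendium(d2)
  expect_identical(a, b)
  expect_false(identical(a$samples[[1]]$value, c$samples[[1]]$value))

  pa <- synth_peak_compendium(d1)
  pb <- synth_peak_compendium(d1)
  expect_identical(pa, pb)
})

test_that("generator output never mutates the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(synth_expression_compendium(synthetic_design(
    n_features = 20, n_groups = 1, per_group = 2, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("realized correlations land near the design targets", {
  set.seed(55)
  rs <- replicate(8, {
    seed <- sample.int(1e6, 1)
    d <- synthetic_design(n_features = 1000, n_groups = 1, per_group = 4,
                          rho_in = 0.8, rho_out = 0.1, seed = seed)
    g <- synth_expression_compendium(d)
    comp <- build_expression_compendium(g$samples, g$metadata)
    cm <- pairwise_matrix(comp)
    mean(cm$r[upper.tri(cm$r)])
  })
  expect_lt(abs(mean(rs) - 0.8), 0.1)

  # peaks need the full design: with very few samples the universe
  # (regions present in >= 1 sample) conditions away jointly-absent
  # regions and attenuates phi
  phis <- replicate(8, {
    seed <- sample.int(1e6, 1)
    d <- synthetic_design(n_features = 1000, n_groups = 5, per_group = 4,
                          rho_in = 0.8, rho_out = 0.1, seed = seed)
    g <- synth_peak_compendium(d)
    comp <- build_peak_compendium(g$samples, g$metadata)
    cm <- pairwise_matrix(comp)
    grp <- g$truth[cm$ids]
    within <- outer(grp, grp, "==") & upper.tri(cm$r)
    mean(cm$r[within])
  })
  expect_lt(abs(mean(phis) - 0.8), 0.1)
})

test_that("tetrachoric inversion is consistent at and away from density 0.5", {
  # closed form at density 0.5
  expect_equal(seqcor:::phi_to_latent(0.8, 0.5), sin(pi * 0.8 / 2),
               tolerance = 1e-12)
  # numeric route agrees with the closed form where both apply
  expect_equal(seqcor:::phi_to_latent(0.3, 0.5000001), sin(pi * 0.3 / 2),
               tolerance = 1e-4)
  expect_identical(seqcor:::phi_to_latent(0, 0.3), 0)
  expect_error(seqcor:::phi_to_latent(1.2, 0.5), class = "seqcor_usage_error")
})

test_that("generated files are valid reader input with zero warnings", {
  d <- synthetic_design(n_features = 60, n_groups = 2, per_group = 2,
                        seed = 12)
  g <- synth_peak_compendium(d)
  p <- tempfile(fileext = ".bed")
  expect_no_warning(write_peak_file(g$samples[[1]], p))
  expect_no_warning(s <- read_peak_file(p, sample_name = "x"))
  expect_identical(s$intervals, g$samples[[1]]$intervals)

  ge <- synth_expression_compendium(d)
  p2 <- tempfile(fileext = ".tsv")
  write_expression_table(ge$samples[[1]], p2)
  expect_no_warning(s2 <- read_expression_table(p2, sample_name = "x"))
  expect_identical(s2$value, ge$samples[[1]]$value)
  expect_identical(s2$gene_id, ge$samples[[1]]$gene_id)
})

test_that("truth labels always match the metadata group attribute", {
  d <- synthetic_design(n_features = 50, n_groups = 3, per_group = 2,
                        seed = 8)
  for (gen in list(synth_expression_compendium(d), synth_peak_compendium(d),
                   synth_cage_compendium(d))) {
    expect_identical(unname(gen$truth[gen$metadata$experiment_id]),
                     gen$metadata$group)
  }
})

test_that("perturbation is deterministic, identity at zero intensity and
           monotone on average", {
  d <- synthetic_design(n_features = 400, n_groups = 1, per_group = 2,
                        seed = 4)
  g <- synth_expression_compendium(d)
  s <- g$samples[[1]]
  expect_identical(perturb_sample(s, 0, seed = 1), s)
  expect_identical(perturb_sample(s, 0.5, seed = 3),
                   perturb_sample(s, 0.5, seed = 3))
  expect_false(identical(perturb_sample(s, 0.5, seed = 3),
                         perturb_sample(s, 0.5, seed = 4)))

  comp <- build_expression_compendium(g$samples, g$metadata)
  base <- project_expression(s, comp)$vector
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  mean_r <- vapply(grid, function(f) {
    mean(vapply(1:10, function(seed) {
      v <- project_expression(perturb_sample(s, f, seed), comp)$vector
      pearson(base, v)
    }, numeric(1L)))
  }, numeric(1L))
  expect_identical(mean_r[1], 1)
  expect_true(all(diff(mean_r) < 0))
})
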