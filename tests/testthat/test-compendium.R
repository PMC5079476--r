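test_that("region universe merges overlapping and bookended intervals", {
  s1 <- peak_sample("a", data.frame(chrom = "chr1", start = 100, end = 200))
  s2 <- peak_sample("b", data.frame(chrom = "chr1", start = 150, end = 250))
  u <- build_region_universe(list(s1, s2))
  expect_identical(u$regions,
                   data.frame(chrom = "chr1", start = 100, end = 250))

  # bookended (end == start, half-open: no shared base) still fuse
  s3 <- peak_sample("c", data.frame(chrom = "chr1", start = 250, end = 300))
  u2 <- build_region_universe(list(s1, s2, s3))
  expect_identical(u2$regions$end, 300)

  # disjoint chromosomes stay separate, chr1 before chr2
  s4 <- peak_sample("d", data.frame(chrom = "chr2", start = 100, end = 200))
  u3 <- build_region_universe(list(s1, s4))
  expect_identical(u3$regions$chrom, c("chr1", "chr2"))

  expect_error(build_region_universe(list()), "length")
})

test_that("universe equals the O(n^2) pairwise-merge oracle on random input", {
  set.seed(42)
  g <- small_genome()
  for (i in 1:25) {
    iv <- rand_intervals(sample(5:30, 1), g, max_len = 5e5)
    u <- build_region_universe(list(peak_sample("x", iv)))
    expect_equal(u$regions, oracle_merge(iv), ignore_attr = TRUE)
  }
})

test_that("universe coverage matches a per-base oracle and contains each input", {
  set.seed(7)
  g <- small_genome(chrom_len = 1e4)
  for (i in 1:10) {
    iv <- rand_intervals(sample(4:20, 1), g, max_len = 2000)
    u <- build_region_universe(list(peak_sample("x", iv)))
    expect_identical(oracle_coverage(u$regions, g), oracle_coverage(iv, g))
    # every input interval lies entirely inside exactly one universe region
    for (j in seq_len(nrow(iv))) {
      inside <- u$regions$chrom == iv$chrom[j] &
        u$regions$start <= iv$start[j] & u$regions$end >= iv$end[j]
      expect_identical(sum(inside), 1L)
    }
  }
})

test_that("binarization follows half-open overlap semantics", {
  u <- region_universe(data.frame(chrom = "chr1", start = 100, end = 200))
  inside <- peak_sample("s", data.frame(chrom = "chr1", start = 150, end = 160))
  expect_identical(binarize_peaks(inside, u), 1L)
  # bookended intervals share no base: no overlap
  book <- peak_sample("s", data.frame(chrom = "chr1", start = 200, end = 300))
  expect_identical(binarize_peaks(book, u), 0L)
  # 1 bp overlap is enough
  onebp <- peak_sample("s", data.frame(chrom = "chr1", start = 199, end = 300))
  expect_identical(binarize_peaks(onebp, u), 1L)
  empty <- peak_sample("s", data.frame(chrom = character(0),
                                       start = numeric(0), end = numeric(0)))
  expect_identical(binarize_peaks(empty, u), 0L)
})

test_that("binarization equals the O(n*m) all-pairs oracle on random input", {
  set.seed(13)
  g <- small_genome()
  for (i in 1:25) {
    uiv <- oracle_merge(rand_intervals(sample(5:25, 1), g, max_len = 3e5))
    siv <- rand_intervals(sample(1:25, 1), g, max_len = 3e5)
    u <- region_universe(uiv)
    s <- peak_sample("s", siv)
    expect_identical(binarize_peaks(s, u), oracle_binarize(siv, uiv))
  }
})

test_that("peak compendium columns are never empty and reflect structure", {
  tp <- tiny_peak_compendium()
  expect_true(all(colSums(tp$comp$matrix) >= 1))

  # identical samples give identical all-ones columns
  s <- peak_sample("a", data.frame(chrom = "chr1", start = c(0, 500),
                                   end = c(100, 600)))
  s2 <- peak_sample("b", s$intervals)
  md <- data.frame(experiment_id = c("a", "b"), stringsAsFactors = FALSE)
  c2 <- build_peak_compendium(list(s, s2), md)
  expect_identical(unname(c2$matrix), matrix(1, 2, 2))

  # disjoint chromosomes give a block-diagonal pattern
  sA <- peak_sample("a", data.frame(chrom = "chr1", start = c(0, 500),
                                    end = c(100, 600)))
  sB <- peak_sample("b", data.frame(chrom = "chr2", start = 10, end = 20))
  cb <- build_peak_compendium(list(sA, sB), md)
  expect_identical(unname(cb$matrix),
                   matrix(c(1, 1, 0, 0, 0, 1), ncol = 2))
  expect_identical(colSums(cb$matrix), c(a = 2, b = 1))

  expect_error(build_peak_compendium(list(), md), "no peak samples",
               class = "seqcor_data_error")
  expect_error(build_peak_compendium(list(sA), md[0, , drop = FALSE]),
               "missing records", class = "seqcor_data_error")
})

test_that("expression compendium log-scales with union features and zero fill", {
  md1 <- data.frame(experiment_id = "e1", stringsAsFactors = FALSE)
  c0 <- build_expression_compendium(list(expression_sample("e1", "g1", 0)),
                                    md1)
  expect_identical(unname(c0$matrix), matrix(0, 1, 1))  # log2(0 + 1)
  c3 <- build_expression_compendium(list(expression_sample("e1", "g1", 3)),
                                    md1)
  expect_identical(unname(c3$matrix), matrix(2, 1, 1))  # log2(3 + 1)

  # partial overlap: union rows, absent entries log(pseudocount)
  sA <- expression_sample("e1", c("g1", "g2"), c(3, 1))
  sB <- expression_sample("e2", c("g2", "g3"), c(7, 15))
  md <- data.frame(experiment_id = c("e1", "e2"), stringsAsFactors = FALSE)
  cc <- build_expression_compendium(list(sA, sB), md, pseudocount = 1,
                                    log_base = 2)
  expect_identical(rownames(cc$matrix), c("g1", "g2", "g3"))
  expect_equal(unname(cc$matrix),
               matrix(c(2, 1, 0, 0, 3, 4), ncol = 2), tolerance = 1e-15)
})

test_that("log transform is strictly monotone within a column", {
  set.seed(5)
  v <- stats::runif(50, 0, 100)
  s <- expression_sample("e1", sprintf("g%02d", 1:50), v)
  cc <- build_expression_compendium(
    list(s), data.frame(experiment_id = "e1"), pseudocount = 1, log_base = 2)
  expect_identical(order(cc$matrix[, 1]), order(v))
})

test_that("CAGE compendium sums scores per region before the log", {
  md <- data.frame(experiment_id = "s1", stringsAsFactors = FALSE)
  one <- peak_sample("s1", data.frame(chrom = "chr1", start = 10, end = 20,
                                      score = 3), scored = TRUE)
  cc <- build_cage_compendium(list(one), md)
  expect_identical(unname(cc$matrix), matrix(2, 1, 1))  # log2(3 + 1)

  # two intervals of one sample falling in one merged region: sum then log
  two <- peak_sample("s1", data.frame(chrom = "chr1", start = c(10, 15),
                                      end = c(20, 30), score = c(1, 2)),
                     scored = TRUE)
  cc2 <- build_cage_compendium(list(two), md)
  expect_identical(unname(cc2$matrix), matrix(2, 1, 1))  # log2(1 + 2 + 1)

  unscored <- peak_sample("s1", data.frame(chrom = "chr1", start = 1, end = 5))
  expect_error(build_cage_compendium(list(unscored), md), "unscored",
               class = "seqcor_data_error")
})

test_that("metadata subsetting selects columns without touching values", {
  tc <- tiny_expression_compendium()
  sub <- subset_compendium(tc$comp, list(cell_type = "a"))
  expect_identical(experiment_ids(sub), c("e1", "e3"))
  expect_identical(sub$matrix, tc$comp$matrix[, c(1, 3)])
  expect_identical(sub$features, tc$comp$features)

  # filter matching everything is the identity
  all_ <- subset_compendium(tc$comp, list(factor = c("X", "Y")))
  expect_identical(all_$matrix, tc$comp$matrix)

  expect_error(subset_compendium(tc$comp, list(nope = "a")),
               "valid keys", class = "seqcor_usage_error")
  expect_error(subset_compendium(tc$comp, list(cell_type = "zzz")),
               "zero experiments", class = "seqcor_data_error")
})

test_that("column subsetting commutes with per-column correlation", {
  d <- synthetic_design(n_features = 300, n_groups = 2, per_group = 4,
                        seed = 21)
  g <- synth_expression_compendium(d, n_user_per_group = 1)
  comp <- build_expression_compendium(g$samples, g$metadata)
  proj <- project_expression(g$user_samples[[1]], comp)

  t_full <- correlate_user(proj, comp)
  sub <- subset_compendium(comp, list(group = "group01"))
  t_sub <- correlate_user(project_expression(g$user_samples[[1]], sub), sub)
  shared <- t_sub$experiment_id
  expect_equal(t_sub$r, t_full$r[match(shared, t_full$experiment_id)],
               tolerance = 1e-15)
})
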