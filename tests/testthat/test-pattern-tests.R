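test_that("flat-line statistic is the population variance of the profile", {
  expect_equal(flat_line_stat(c(I = 2, II = 2, III = 2, IV = 2)), 0)
  expect_equal(flat_line_stat(c(I = 1, II = 2, III = 3, IV = 4)), 1.25)
  # NAT never enters the statistic
  expect_equal(flat_line_stat(c(I = 1, II = 2, III = 3, IV = 4, NAT = 99)),
               1.25)
  expect_error(flat_line_stat(c(I = 1, IV = 3)), ">= 3")
})

test_that("hourglass scores match direct arithmetic on both directions", {
  mods <- stage_modules()
  prof <- c(I = 3, II = 1, III = 1, IV = 3)
  expect_equal(hourglass_score(prof, mods, "reductive"), 2)
  expect_equal(hourglass_score(c(I = 1, II = 1, III = 1, IV = 1), mods,
                               "reductive"), 0)
  expect_equal(hourglass_score(c(I = 1, II = 3, III = 3, IV = 1), mods,
                               "reverse"), 2)

  expect_error(stage_modules(early = "I", mid = "I", late = "IV"),
               "disjoint")
  expect_error(stage_modules(early = character(0)), "non-empty")
  expect_error(hourglass_score(prof, stage_modules("I", "II", "III")),
               "cover")
})

test_that("reductive and reverse scores satisfy the min/max identity", {
  mods <- stage_modules()
  set.seed(13)
  for (rep in 1:50) {
    prof <- setNames(rnorm(4), c("I", "II", "III", "IV"))
    red <- hourglass_score(prof, mods, "reductive")
    rev_ <- hourglass_score(prof, mods, "reverse")
    x <- prof[["I"]] - mean(prof[c("II", "III")])
    y <- prof[["IV"]] - mean(prof[c("II", "III")])
    expect_equal(red + rev_, min(x, y) - max(x, y))
    expect_lte(red + rev_, 1e-12)
    if (abs(x - y) > 1e-12) expect_lt(red + rev_, 0)
  }
})

test_that("permutation test is reproducible, bounded and degenerate-safe", {
  cfg <- simulation_config(n_genes = 300, samples_per_stage =
                             c(I = 3L, II = 3L, III = 3L, IV = 3L, NAT = 0L),
                           pattern = "flat", seed = 5)
  uni <- generate_universe(cfg)
  x <- generate_expression(cfg, uni$ages)

  r1 <- permutation_test(x, uni$ages, "flat_line", B = 200, seed = 99)
  r2 <- permutation_test(x, uni$ages, "flat_line", B = 200, seed = 99)
  expect_identical(r1, r2)
  expect_gte(r1$p_value, 1 / 201)
  expect_lte(r1$p_value, 1)

  # all genes in one stratum: observed and every permuted statistic are 0
  const <- age_map(names(uni$ages), rep(3L, length(uni$ages)))
  r0 <- permutation_test(x, const, "flat_line", B = 200, seed = 1)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  expect_error(permutation_test(x, uni$ages, "flat_line", B = 50, seed = 1),
               "B must be")
  expect_error(permutation_test(x, uni$ages, "flat_line", B = 200),
               "seed")
})

test_that("permuting stratum labels preserves the expression structure", {
  # the null permutes gene -> stratum only; per-sample expression totals and
  # the multiset of stratum values are untouched
  set.seed(21)
  s <- sample.int(14L, 100, replace = TRUE)
  perm <- sample(s)
  expect_identical(sort(perm), sort(s))
})

test_that("planted hourglass is detected and its mirror is not (seed-fixed)", {
  cfg <- simulation_config(pattern = "hourglass", effect_size = 2, seed = 7)
  uni <- generate_universe(cfg)
  x <- generate_expression(cfg, uni$ages)

  red <- permutation_test(x, uni$ages, "reductive_hourglass",
                          B = 1000, seed = 7)
  expect_lt(red$p_value, 0.05)
  # regression: with every permuted score below the observed one the
  # empirical p sits at its add-one floor
  expect_equal(red$p_value, 1 / 1001)
  expect_gt(red$statistic, 1.5)  # planted separation of ~2 index units

  rev_ <- permutation_test(x, uni$ages, "reverse_hourglass",
                           B = 1000, seed = 7)
  expect_gt(rev_$p_value, 0.5)

  # mean-of-sample-indices aggregation sees the same planted pattern
  red2 <- permutation_test(x, uni$ages, "reductive_hourglass", B = 500,
                           seed = 7, aggregation = "mean_of_sample_indices")
  expect_lt(red2$p_value, 0.05)
})
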