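test_that("library normalization scales every column to the target total", {
  x <- tiny_expression()
  n1 <- normalize_library(x, scale = 1e6)
  expect_equal(unname(colSums(n1$counts)), rep(1e6, 5))
  expect_identical(n1$stages, x$stages)

  # hand proportions: column (1, 3) at scale 100 -> (25, 75)
  y <- staged_expression(matrix(c(1, 3), 2, 1,
                                dimnames = list(c("a", "b"), "s")), "I")
  expect_equal(unname(normalize_library(y, 100)$counts[, 1]), c(25, 75))

  z <- staged_expression(matrix(c(0, 0), 2, 1,
                                dimnames = list(c("a", "b"), "zz")), "I")
  expect_error(normalize_library(z), "zz")
})

test_that("the per-sample index is the expression-weighted mean stratum", {
  # constant stratum: index equals it regardless of expression
  flat <- age_map(c("g1", "g2", "g3"), c(2L, 2L, 2L))
  expect_equal(compute_index_sample(c(g1 = 5, g2 = 1, g3 = 0.3), flat), 2)

  # hand weighted mean (1*3 + 3*1) / 4
  am <- age_map(c("g1", "g2"), c(1L, 3L))
  expect_equal(compute_index_sample(c(g1 = 3, g2 = 1), am), 1.5)

  # zero-expression genes contribute nothing
  am2 <- age_map(c("g1", "g2"), c(1L, 14L))
  expect_equal(compute_index_sample(c(g1 = 0, g2 = 5), am2), 14)

  expect_error(compute_index_sample(c(g1 = 0, g2 = 0), am2),
               "positive expression")
  expect_error(compute_index_sample(c(zz = 1), am2), "positive expression")
})

test_that("index properties: scale invariance, bounds, monotonicity, oracle", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    genes <- sprintf("g%02d", seq_len(n))
    am <- age_map(genes, sample.int(14L, n, replace = TRUE))
    e <- setNames(rexp(n), genes)

    idx <- compute_index_sample(e, am)
    expect_equal(compute_index_sample(e * runif(1, 0.1, 50), am), idx)

    contrib <- unclass(am)[names(e)[e > 0]]
    expect_gte(idx, min(contrib))
    expect_lte(idx, max(contrib))

    # raising the oldest-stratum gene's expression never lowers the index
    top <- names(which.max(unclass(am)))
    e2 <- e; e2[top] <- e2[top] + runif(1, 0, 5)
    expect_gte(compute_index_sample(e2, am), idx - 1e-12)

    expect_equal(idx, index_oracle(e, am), tolerance = 1e-12)
  }
})

test_that("stage aggregation matches hand computation both ways", {
  # single sample: both aggregations reduce to that sample's index
  x1 <- staged_expression(matrix(c(3, 1), 2, 1,
                                 dimnames = list(c("g1", "g2"), "s1")), "I")
  am <- age_map(c("g1", "g2"), c(1L, 3L))
  for (agg in c("mean_expression", "mean_of_sample_indices")) {
    p <- compute_profile(x1, am, aggregation = agg, normalize = FALSE)
    expect_equal(unname(p$per_stage["I"]), 1.5)
  }

  # two samples (2,0) and (0,2): stage-mean expression (1,1) -> index 2,
  # and per-sample indices 1 and 3 -> mean 2 (agreement is coincidental)
  x2 <- staged_expression(matrix(c(2, 0, 0, 2), 2, 2,
                                 dimnames = list(c("g1", "g2"),
                                                 c("s1", "s2"))),
                          c("I", "I"))
  pm <- compute_profile(x2, am, aggregation = "mean_expression",
                        normalize = FALSE)
  expect_equal(unname(pm$per_stage["I"]), 2)
  ps <- compute_profile(x2, am, aggregation = "mean_of_sample_indices",
                        normalize = FALSE)
  expect_equal(unname(ps$per_stage["I"]), 2)
  expect_equal(unname(ps$per_sample), c(1, 3))
})

test_that("profiles drop unannotated genes, order stages, flag TAI vs TDI", {
  x <- tiny_expression()
  partial <- age_map(c("g1", "g2"), c(1L, 7L))  # g3 unannotated
  p <- compute_profile(x, partial)
  expect_identical(p$n_genes_used, 2L)
  expect_identical(p$n_genes_dropped, 1L)
  expect_identical(names(p$per_stage), c("I", "II", "III", "IV", "NAT"))
  expect_identical(p$index_kind, "TAI")

  dm <- divergence_map(sprintf("g%02d", 1:10), (1:10) / 20)
  counts <- matrix(rpois(20, 30), nrow = 10,
                   dimnames = list(sprintf("g%02d", 1:10), c("a", "b")))
  xd <- staged_expression(counts, c("I", "II"))
  pd <- compute_profile(xd, rank_deciles(dm))
  expect_identical(pd$index_kind, "TDI")
  expect_true(all(pd$per_sample >= 1 & pd$per_sample <= 10))
})
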