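test_that("stratum contingency tables count the four cells correctly", {
  bg <- age_map(c("g1", "g2", "g3"), c(2L, 2L, 5L))
  tab <- stratum_contingency("g1", bg, 2L)
  expect_identical(as.integer(tab), c(1L, 1L, 0L, 1L))  # a, c, b, d

  empty <- stratum_contingency(character(0), bg, 2L)
  expect_identical(as.integer(empty), c(0L, 2L, 0L, 1L))

  expect_error(stratum_contingency("gX", bg, 2L), "gX")
})

test_that("fisher_exact matches enumeration, fisher.test and hand values", {
  # hand value: ((2,0),(0,2)) -> p = 2 * (1/6) = 1/3
  t1 <- matrix(c(2, 0, 0, 2), 2)
  r1 <- fisher_exact(t1)
  expect_equal(r1$p_value, 1 / 3)
  expect_identical(r1$odds_ratio, Inf)

  # zero margin: only one table possible
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2))$p_value, 1)

  # symmetric table
  r2 <- fisher_exact(matrix(c(1, 1, 1, 1), 2))
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$p_value, 1)

  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "negative")

  # random tables: agree with the lchoose enumeration oracle and with
  # stats::fisher.test's two-sided p
  set.seed(3)
  for (rep in 1:50) {
    tab <- matrix(rpois(4, 6), 2)
    r <- fisher_exact(tab)
    expect_equal(r$p_value, fisher_oracle(tab), tolerance = 1e-12)
    expect_equal(r$p_value, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("chi2_bootstrap handles the null identity and planted enrichment", {
  # composition exactly proportional to background -> chi2 = 0, p = 1
  bg <- age_map(sprintf("g%03d", 1:100), rep(1:2, each = 50))
  deg <- c(sprintf("g%03d", 1:5), sprintf("g%03d", 51:55))
  r <- chi2_bootstrap(deg, bg, n_bootstrap = 200, seed = 1)
  expect_equal(r$chi2, 0)
  expect_equal(r$bootstrap_p, 1)
  expect_identical(r$chi2_df, 1L)
  expect_equal(sum(r$per_stratum$count_deg), length(deg))

  # extreme planted signal: all DEGs in stratum 1 of a uniform background
  bg2 <- age_map(sprintf("g%04d", 1:1000), rep(1:2, each = 500))
  deg2 <- sprintf("g%04d", 1:50)
  r2 <- chi2_bootstrap(deg2, bg2, n_bootstrap = 10000, seed = 1)
  expect_equal(r2$chi2, 50)  # (50-25)^2/25 * 2
  expect_lte(r2$bootstrap_p, 0.001)
  expect_gte(r2$bootstrap_p, 1 / 10001)

  # determinism and BH monotonicity
  r3 <- chi2_bootstrap(deg2, bg2, n_bootstrap = 500, seed = 42)
  r4 <- chi2_bootstrap(deg2, bg2, n_bootstrap = 500, seed = 42)
  expect_identical(r3, r4)
  ord <- order(r3$per_stratum$fisher_p)
  expect_true(all(diff(r3$per_stratum$fisher_q[ord]) >= -1e-12))
  expect_equal(r3$per_stratum$fisher_q,
               p.adjust(r3$per_stratum$fisher_p, "BH"))

  expect_error(chi2_bootstrap(character(0), bg, 200, seed = 1), "empty")
  expect_error(chi2_bootstrap(deg, bg, 50, seed = 1), ">= 100")
})

test_that("median log2FC summaries fill cells and leave gaps missing", {
  ages <- age_map(c("a", "b", "c", "d"), c(1L, 1L, 2L, 4L))
  deg <- data.frame(
    gene_id = c("a", "b", "c", "a"),
    log2fc = c(1, 3, -2, 0.5),
    padj = 0.01,
    stage = c("I", "I", "I", "II"),
    cancer_type = "T")
  med <- median_log2fc_by_stratum(deg, ages)
  expect_equal(med["1", "I"], 2)        # median of {1, 3}
  expect_equal(med["2", "I"], -2)       # singleton
  expect_equal(med["1", "II"], 0.5)
  expect_true(is.na(med["4", "I"]))     # stratum absent from the DEG list
  expect_true(is.na(med["3", "I"]))
  expect_identical(dim(med), c(4L, 4L))

  expect_error(median_log2fc_by_stratum(
    data.frame(gene_id = "zz", log2fc = 1, stage = "I"), ages), "zz")
})

test_that("naive log2FC helper does the arithmetic it promises", {
  expect_equal(naive_log2fc(4, 1, pseudocount = 1), log2(5 / 2))
  expect_equal(naive_log2fc(c(3, 7), c(3, 7)), c(0, 0))
  expect_equal(naive_log2fc(0, 0, pseudocount = 1), 0)
  expect_error(naive_log2fc(1:3, 1:2), "equal length")
  expect_error(naive_log2fc(1, 1, pseudocount = 0), "pseudocount")
})
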