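test_that("simulation config validates its inputs", {
  expect_s3_class(simulation_config(), "sim_config")
  expect_error(simulation_config(stratum_probs = c(0.5, 0.4)), "length")
  expect_error(simulation_config(n_strata = 2,
                                 stratum_probs = c(0.7, 0.4)), "sum to 1")
  expect_error(simulation_config(enriched_strata = 15L), "1..n_strata")
  expect_error(simulation_config(enrichment_fold = 0.5), "enrichment_fold")
})

test_that("the simulated universe follows the configured age distribution", {
  # degenerate distribution: every gene lands in stratum 5
  probs <- rep(0, 14); probs[5] <- 1
  cfg <- simulation_config(n_genes = 100, stratum_probs = probs, seed = 2)
  uni <- generate_universe(cfg)
  expect_true(all(unclass(uni$ages) == 5L))
  expect_true(all(uni$divergence >= 0))

  # uniform draw: per-stratum counts within 3 sd of n/14
  cfg2 <- simulation_config(n_genes = 10000, seed = 8)
  u2 <- generate_universe(cfg2)
  counts <- tabulate(unclass(u2$ages), nbins = 14)
  expected <- 10000 / 14
  sd3 <- 3 * sqrt(10000 * (1 / 14) * (13 / 14))
  expect_true(all(abs(counts - expected) < sd3))

  # determinism
  expect_identical(generate_universe(cfg2), u2)
})

test_that("simulated expression is reproducible and respects the config", {
  cfg <- simulation_config(n_genes = 400, seed = 31)
  uni <- generate_universe(cfg)
  x1 <- generate_expression(cfg, uni$ages)
  x2 <- generate_expression(cfg, uni$ages)
  expect_identical(x1, x2)
  expect_identical(dim(x1$counts), c(400L, 36L))
  expect_identical(as.integer(table(x1$stages)[c("I", "NAT")]), c(8L, 4L))
  expect_true(all(x1$counts >= 0))
  expect_true(all(x1$counts == floor(x1$counts)))

  deg1 <- generate_deg_table(cfg, uni$ages)
  expect_identical(deg1, generate_deg_table(cfg, uni$ages))
  expect_identical(nrow(deg1), 4L * cfg$deg_size)
  expect_true(all(deg1$padj >= 0 & deg1$padj <= 0.05))
  # unique genes within each stage list (sampling without replacement)
  expect_false(any(tapply(deg1$gene_id, deg1$stage, anyDuplicated) > 0))
})

test_that("flat simulations give flat expected profiles", {
  # across replicates, stage TAI spread under the flat regime stays within
  # Monte-Carlo noise of zero pattern
  spreads <- vapply(1:30, function(i) {
    cfg <- simulation_config(n_genes = 500, seed = 1000 + i)
    uni <- generate_universe(cfg)
    x <- generate_expression(cfg, uni$ages)
    p <- compute_profile(x, uni$ages)$per_stage[c("I", "II", "III", "IV")]
    max(p) - min(p)
  }, numeric(1))
  # planted patterns at the default effect would put the spread near 2;
  # flat spreads should sit far below that
  expect_lt(mean(spreads), 0.5)
  expect_lt(max(spreads), 1)
})

test_that("planted patterns land where the calibration says they should", {
  cfg <- simulation_config(pattern = "hourglass", effect_size = 2,
                           n_genes = 1500, seed = 17)
  uni <- generate_universe(cfg)
  x <- generate_expression(cfg, uni$ages)
  prof <- compute_profile(x, uni$ages)$per_stage
  score <- hourglass_score(prof, stage_modules(), "reductive")
  expect_gt(score, 0)
  # calibrated separation ~ effect_size (sampling noise allowed)
  expect_equal(score, 2, tolerance = 0.25)

  cfg_r <- simulation_config(pattern = "reverse_hourglass", effect_size = 2,
                             n_genes = 1500, seed = 17)
  x_r <- generate_expression(cfg_r, uni$ages)
  prof_r <- compute_profile(x_r, uni$ages)$per_stage
  expect_gt(hourglass_score(prof_r, stage_modules(), "reverse"), 0)

  # Poisson limit with a large baseline approaches the noise-free analytic
  # expectation of the planted profile
  cfg_p <- simulation_config(pattern = "flat", n_genes = 800,
                             baseline_mean = 5000, baseline_sdlog = 0,
                             dispersion = Inf, seed = 23)
  uni_p <- generate_universe(cfg_p)
  x_p <- generate_expression(cfg_p, uni_p$ages)
  prof_p <- compute_profile(x_p, uni_p$ages)$per_stage
  analytic <- mean(unclass(uni_p$ages))  # equal means -> plain mean stratum
  expect_equal(unname(prof_p["I"]), analytic, tolerance = 0.02)

  # an unattainable effect size errors out instead of silently saturating
  expect_error(generate_expression(
    simulation_config(pattern = "hourglass", effect_size = 50, seed = 1),
    generate_universe(simulation_config(seed = 1))$ages),
    "attainable")
})
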