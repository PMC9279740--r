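test_that("identical configuration and seed give bit-identical simulations", {
  cfg <- sim_config(n_genes = 120, seed = 99)
  s1 <- simulate_factorial_counts(cfg)
  s2 <- simulate_factorial_counts(cfg)
  expect_identical(s1$counts$counts, s2$counts$counts)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_factorial_counts(sim_config(n_genes = 120, seed = 100))
  expect_false(identical(s1$counts$counts, s3$counts$counts))
})

test_that("category quotas are exact under largest-remainder assignment", {
  cfg <- sim_config(n_genes = 1000, seed = 5,
                    category_fractions = c(null = 0.9, single_only = 0,
                                           additive = 0,
                                           synergistic_pos = 0.1,
                                           synergistic_neg = 0,
                                           antagonistic = 0))
  truth <- simulate_factorial_counts(cfg)$truth
  tab <- table(truth$true_category)
  expect_identical(unname(tab[["synergistic_pos"]]), 100L)
  expect_identical(unname(tab[["null"]]), 900L)

  ## fractions that do not divide n evenly: 10 genes over three thirds
  cfg2 <- sim_config(n_genes = 10, seed = 5,
                     category_fractions = c(null = 1/3, single_only = 1/3,
                                            additive = 1/3,
                                            synergistic_pos = 0,
                                            synergistic_neg = 0,
                                            antagonistic = 0))
  tab2 <- table(simulate_factorial_counts(cfg2)$truth$true_category)
  expect_identical(sort(unname(as.integer(tab2)), decreasing = TRUE),
                   c(4L, 3L, 3L))
  expect_identical(unname(tab2[["null"]]), 4L)  # tie goes to the first category
})

test_that("truth table satisfies the per-category effect structure", {
  truth <- simulate_factorial_counts(sim_config(n_genes = 600, seed = 3))$truth
  with(subset(truth, true_category == "null"), {
    expect_true(all(true_x == 0 & true_y == 0 & true_interaction == 0))
  })
  with(subset(truth, true_category == "additive"), {
    expect_true(all(true_interaction == 0))
    expect_true(all(abs(true_x) > 0 & abs(true_y) > 0))
  })
  with(subset(truth, true_category %in% c("synergistic_pos", "synergistic_neg")), {
    expect_true(all(abs(true_interaction) > 0))
    combined <- true_x + true_y + true_interaction
    expect_true(all(abs(combined) > abs(true_x + true_y)))
  })
  with(subset(truth, true_category == "antagonistic"), {
    combined <- true_x + true_y + true_interaction
    expect_true(all(abs(combined) < pmax(abs(true_x), abs(true_y))))
  })
  with(subset(truth, true_category == "single_only"), {
    expect_true(all((true_x == 0) != (true_y == 0)))
    expect_true(all(true_interaction == 0))
  })
})

test_that("null-model simulation has equal condition means within Poisson error", {
  cfg <- sim_config(n_genes = 20, n_replicates = 2000,
                    baseline_log2_mean = 6, baseline_log2_sd = 0,
                    category_fractions = c(null = 1, single_only = 0,
                                           additive = 0, synergistic_pos = 0,
                                           synergistic_neg = 0,
                                           antagonistic = 0),
                    seed = 17)
  sim <- simulate_factorial_counts(cfg)
  x <- sim$counts
  cond_means <- sapply(levels(x$condition), function(cc)
    rowMeans(x$counts[, x$condition == cc, drop = FALSE]))
  rel_err <- abs(cond_means / sim$truth$baseline_mean - 1)
  expect_lt(max(rel_err), 0.02)
})

test_that("expected counts follow the factorial mean model", {
  ## one gene per category, huge replication, check empirical means against
  ## sizefactor * 2^(baseline + x + y + interaction) per condition
  cfg <- sim_config(n_genes = 6, n_replicates = 1000,
                    baseline_log2_mean = 9, baseline_log2_sd = 0,
                    library_size_factors = rep(c(1, 1.5, 0.8, 1.2),
                                               each = 1000),
                    category_fractions = c(null = 1/6, single_only = 1/6,
                                           additive = 1/6,
                                           synergistic_pos = 1/6,
                                           synergistic_neg = 1/6,
                                           antagonistic = 1/6),
                    seed = 8)
  sim <- simulate_factorial_counts(cfg)
  x <- sim$counts
  tr <- sim$truth
  conds <- levels(x$condition)
  in_a <- c(0, 1, 0, 1); in_b <- c(0, 0, 1, 1); in_ab <- c(0, 0, 0, 1)
  sfac <- c(1, 1.5, 0.8, 1.2)  # constant within condition by construction
  for (ci in seq_along(conds)) {
    cols <- x$condition == conds[ci]
    expected <- sfac[ci] * 2^(log2(tr$baseline_mean) + tr$true_x * in_a[ci] +
                              tr$true_y * in_b[ci] +
                              tr$true_interaction * in_ab[ci])
    observed <- rowMeans(x$counts[, cols, drop = FALSE])
    expect_lt(max(abs(observed / expected - 1)), 0.05)
  }
})

test_that("negative-binomial dispersion inflates variance beyond Poisson", {
  base <- sim_config(n_genes = 40, n_replicates = 200,
                     baseline_log2_mean = 8, baseline_log2_sd = 0,
                     category_fractions = c(null = 1, single_only = 0,
                                            additive = 0, synergistic_pos = 0,
                                            synergistic_neg = 0,
                                            antagonistic = 0),
                     seed = 21)
  pois <- simulate_factorial_counts(base)$counts$counts
  nb_cfg <- base; nb_cfg$dispersion <- 0.5
  nb <- simulate_factorial_counts(nb_cfg)$counts$counts
  ## Poisson: var ~ mean (256). NB: var = mu + dispersion * mu^2 >> mu.
  expect_lt(median(apply(pois, 1, var)) / 256, 1.5)
  expect_gt(median(apply(nb, 1, var)), 10 * 256)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(category_fractions = c(null = 0.5, single_only = 0,
                                                 additive = 0,
                                                 synergistic_pos = 0,
                                                 synergistic_neg = 0,
                                                 antagonistic = 0)),
               "sum to 1")
  expect_error(sim_config(library_size_factors = rep(-1, 12)), "positive")
  expect_error(sim_config(dispersion = -0.1), "non-negative")
  expect_error(sim_config(conditions = c("control", "A", "B")), "four")
})
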