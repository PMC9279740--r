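test_that("size factors match forced cases and hand computation", {
  ## two identical samples per condition -> all factors 1
  x <- toy_counts(control = c(10L, 20L, 30L), n_rep = 2)
  expect_equal(unname(size_factors(x, "total-count")), rep(1, 8))
  expect_equal(unname(size_factors(x, "median-of-ratios")), rep(1, 8))

  ## doubling one library: total-count factors scale with the totals and
  ## keep geometric mean 1, so the doubled sample sits at twice its twin
  m <- cbind(c(10L, 20L), c(20L, 40L), c(10L, 20L), c(10L, 20L),
             c(10L, 20L), c(10L, 20L), c(10L, 20L), c(10L, 20L))
  colnames(m) <- paste0("s", 1:8); rownames(m) <- c("g1", "g2")
  x2 <- count_matrix(m, rep(c("control", "A", "B", "AB"), each = 2))
  f <- size_factors(x2, "total-count")
  totals <- colSums(m)
  expect_equal(unname(f), unname(totals / exp(mean(log(totals)))),
               tolerance = 1e-12)
  expect_equal(unname(f[2] / f[1]), 2, tolerance = 1e-12)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  ## 3-gene toy matrix: brute-force median of per-gene ratios to the
  ## geometric-mean reference, rescaled to geometric mean 1
  m3 <- cbind(c(4L, 10L, 100L), c(8L, 30L, 100L), c(4L, 10L, 100L),
              c(4L, 10L, 100L))
  colnames(m3) <- paste0("s", 1:4); rownames(m3) <- paste0("g", 1:3)
  x3 <- count_matrix(m3, c("control", "A", "B", "AB"))
  ref <- apply(m3, 1, function(r) exp(mean(log(r))))
  manual <- apply(m3 / ref, 2, median)
  manual <- manual / exp(mean(log(manual)))
  expect_equal(unname(size_factors(x3, "median-of-ratios")), unname(manual),
               tolerance = 1e-12)
})

test_that("median-of-ratios factors agree with the DESeq2 estimator", {
  sim <- simulate_factorial_counts(sim_config(
    n_genes = 300, seed = 12,
    library_size_factors = rep(c(0.7, 1, 1.3, 1.6, 0.9, 1.1), 2)))
  f_pkg <- size_factors(sim$counts, "median-of-ratios")
  f_ref <- DESeq2::estimateSizeFactorsForMatrix(sim$counts$counts)
  f_ref <- f_ref / exp(mean(log(f_ref)))
  expect_equal(unname(f_pkg), unname(f_ref), tolerance = 1e-8)
})

test_that("all-zero samples are rejected by name", {
  m <- cbind(c(5L, 5L), c(0L, 0L), c(5L, 5L), c(5L, 5L))
  colnames(m) <- c("ok1", "dead", "ok2", "ok3")
  rownames(m) <- c("g1", "g2")
  x <- count_matrix(m, c("control", "A", "B", "AB"))
  expect_error(size_factors(x), "dead")
})

test_that("log2 fold-change point estimates match their definition", {
  x <- toy_counts(control = rep(10L, 3), a = rep(20L, 3), b = rep(10L, 3),
                  ab = rep(40L, 3), n_rep = 3)
  eff <- estimate_effects(x, factors = rep(1, 12), pseudocount = 0)
  a_row <- eff[eff$contrast == "A-vs-control" & eff$gene_id == "g1", ]
  expect_equal(a_row$log2_fch, 1)
  b_row <- eff[eff$contrast == "B-vs-control" & eff$gene_id == "g1", ]
  expect_equal(b_row$log2_fch, 0)   # treatment identical to control
  ab_row <- eff[eff$contrast == "AB-vs-control" & eff$gene_id == "g1", ]
  expect_equal(ab_row$log2_fch, 2)
})

test_that("delta-method standard error matches formula and bootstrap", {
  x <- toy_counts(control = rep(10L, 1), a = rep(20L, 1), n_rep = 3)
  eff <- estimate_effects(x, factors = rep(1, 12), pseudocount = 0)
  se <- eff[eff$contrast == "A-vs-control", "se"]
  expect_equal(se, sqrt(1 / 60 + 1 / 30) / log(2), tolerance = 1e-12)

  ## parametric bootstrap oracle: sd of log2 ratio of Poisson means
  set.seed(401)
  n_boot <- 1e5
  mt <- rowMeans(matrix(rpois(3 * n_boot, 20), ncol = 3))
  mc <- rowMeans(matrix(rpois(3 * n_boot, 10), ncol = 3))
  boot_se <- sd(log2(mt / mc))
  expect_lt(abs(se / boot_se - 1), 0.10)
})

test_that("exact Poisson test matches analytic and enumerated tails", {
  ## all-zero gene: p = 1, never differentially expressed
  x0 <- toy_counts(control = c(0L, 50L), ab = c(0L, 50L), n_rep = 3)
  de0 <- poisson_de_test(x0, factors = rep(1, 12))
  expect_equal(de0$p_raw[1], 1)
  expect_false(de0$is_de[1])

  ## 10 vs 0 at equal exposure: p = 2 * 0.5^10
  x1 <- toy_counts(control = c(0L, 20L), ab = c(10L, 20L), n_rep = 1)
  de1 <- poisson_de_test(x1, factors = rep(1, 4))
  expect_equal(de1$p_raw[1], 2 * 0.5^10, tolerance = 1e-15)

  ## exhaustive enumeration over a grid of totals <= 50, unequal exposure
  cases <- expand.grid(k_t = c(0L, 1L, 3L, 7L, 19L, 25L),
                       k_c = c(0L, 2L, 5L, 11L, 25L))
  counts <- cbind(cases$k_c, 1L, 1L, cases$k_t)
  rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  colnames(counts) <- paste0("s", 1:4)
  xg <- count_matrix(counts, c("control", "A", "B", "AB"))
  fac <- c(1.4, 1, 1, 0.6)
  de <- poisson_de_test(xg, factors = fac, condition = "AB",
                        reference = "control")
  p0 <- 0.6 / (0.6 + 1.4)   # exposure ratio is invariant to rescaling
  oracle <- mapply(enum_binom_p, cases$k_t, cases$k_c,
                   MoreArgs = list(p0 = p0))
  expect_lt(max(abs(de$p_raw - oracle)), 1e-12)
})

test_that("swapping treatment and reference negates the effect, keeps p", {
  sim <- simulate_factorial_counts(sim_config(n_genes = 80, seed = 31))
  f <- size_factors(sim$counts)
  fwd <- poisson_de_test(sim$counts, f, condition = "AB", reference = "control")
  rev <- poisson_de_test(sim$counts, f, condition = "control", reference = "AB")
  expect_equal(rev$log2_fch, -fwd$log2_fch, tolerance = 1e-12)
  expect_equal(rev$p_raw, fwd$p_raw, tolerance = 1e-12)
})

test_that("results are invariant to the overall scale of size factors", {
  sim <- simulate_factorial_counts(sim_config(n_genes = 60, seed = 32))
  f <- size_factors(sim$counts)
  a <- poisson_de_test(sim$counts, f)
  b <- poisson_de_test(sim$counts, f * 37.5)
  expect_equal(a$log2_fch, b$log2_fch, tolerance = 1e-12)
  expect_equal(a$p_raw, b$p_raw, tolerance = 1e-12)
  ea <- estimate_effects(sim$counts, f)
  eb <- estimate_effects(sim$counts, f * 37.5)
  expect_equal(ea$log2_fch, eb$log2_fch, tolerance = 1e-12)
  expect_equal(ea$se, eb$se, tolerance = 1e-12)
})

test_that("BH adjustment reproduces analytic cases and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.005, 0.04)), c(0.01, 0.04))
  p <- c(0.001, 0.2, 0.04, 1, 0.04)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_identical(order(q), order(p))  # ranking preserved
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, -0.1)), "\\[0, 1\\]")
})
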