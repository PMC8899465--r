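test_that("scenario configuration validates its fields", {
  expect_error(scenario_config(ld = c(0.5, 0.2)), "lo < hi")
  expect_error(scenario_config(rho = -0.5, time_grid = 1:3),
               "compound symmetry")
  expect_error(scenario_config(region_class = "weird"))
  cfg <- scenario_config(n = 100, L = 20, region_class = "rare")
  expect_s3_class(cfg, "lfdat_scenario")
})

test_that("LE genotypes respect their MAF class and are reproducible", {
  cfg <- scenario_config(n = 300, L = 40, region_class = "rare", seed = 7)
  g <- simulate_genotypes_le(cfg)
  expect_true(all(g$maf > 0.0005 & g$maf < 0.01))
  expect_true(all(g$sample_maf <= 0.02))  # drawn MAF + sampling noise
  expect_true(all(g$G %in% 0:2))
  expect_equal(diff(range(diff(g$positions))), 0)  # equally spaced

  g2 <- simulate_genotypes_le(cfg)
  expect_identical(g$G, g2$G)
  expect_identical(g$maf, g2$maf)

  cfg_c <- scenario_config(n = 2000, L = 30, region_class = "common",
                           seed = 11)
  gc <- simulate_genotypes_le(cfg_c)
  expect_true(all(gc$maf > 0.05 & gc$maf < 0.5))
  # empirical allele frequency tracks the drawn parameter (binomial 4 SE)
  p_hat <- colMeans(gc$G) / 2
  se <- sqrt(gc$maf * (1 - gc$maf) / (2 * 2000))
  expect_true(all(abs(p_hat - gc$maf) < 4.5 * se |
                    abs((1 - p_hat) - gc$maf) < 4.5 * se))
})

test_that("mixture regions draw the stated class proportions", {
  set.seed(13)
  cfg <- scenario_config(n = 10, L = 600, region_class = "mixture1")
  g <- simulate_genotypes_le(cfg)
  frac_common <- mean(g$maf > 0.05)
  expect_lt(abs(frac_common - 0.2), 3 * sqrt(0.2 * 0.8 / 600))

  cfg2 <- scenario_config(n = 10, L = 600, region_class = "mixture2")
  g2 <- simulate_genotypes_le(cfg2)
  expect_lt(abs(mean(g2$maf > 0.05) - 0.8), 3 * sqrt(0.2 * 0.8 / 600))
})

test_that("null phenotypes have the configured moments and correlation", {
  cfg <- scenario_config(n = 2000, L = 5, seed = 17)
  ph <- simulate_null_phenotypes(cfg)
  n <- 2000
  expect_true(all(abs(colMeans(ph$Y) - 1) < 3 / sqrt(n)))
  v <- apply(ph$Y, 2, var)
  expect_true(all(abs(v - 1) < 3 * sqrt(2 / (n - 1))))
  r19 <- cor(ph$Y[, 1], ph$Y[, 9])
  expect_lt(abs(r19 - 0.5), 3 * (1 - 0.5^2) / sqrt(n))

  cfg0 <- scenario_config(n = 2000, L = 5, rho = 0, seed = 19)
  ph0 <- simulate_null_phenotypes(cfg0)
  offdiag <- cor(ph0$Y)[upper.tri(diag(9))]
  expect_lt(max(abs(offdiag)), 4 / sqrt(n))
})

test_that("effect sizes follow the MAF-dependent formula", {
  G <- matrix(rbinom(200, 2, 0.3), 50, 4)
  geno <- genotype_region(G, c(100, 300, 600, 900), region_length = 1000,
                          maf = rep(0.01, 4))
  cfg <- scenario_config(n = 50, L = 4, c = 3, causal_prop = 0.25)
  set.seed(23)
  eff <- make_effect(cfg, geno)
  # c = 3, MAF = 0.01: eta = ln(3) * |log10(0.01)| / 2 = ln(3)
  expect_equal(eff$eta, rep(log(3), length(eff$causal_indices)))
  expect_length(eff$causal_indices, 1L)  # max(1, round(0.25*4)) = 1
  expect_equal(eff$signs, 1)

  cfg_many <- scenario_config(n = 50, L = 4, c = 5, causal_prop = 1,
                              neg_prop = 0.5)
  eff2 <- make_effect(cfg_many, geno)
  expect_length(eff2$causal_indices, 4L)
  expect_equal(sum(eff2$signs == -1), 2L)

  cfg100 <- scenario_config(n = 20, L = 100, causal_prop = 0.01)
  g100 <- simulate_genotypes_le(scenario_config(n = 20, L = 100,
                                                region_class = "common",
                                                seed = 3))
  expect_length(make_effect(cfg100, g100)$causal_indices, 1L)
})

test_that("the gene-switching time effects vanish and peak where stated", {
  th2 <- theta_function("case2")
  expect_equal(th2(3), 0, tolerance = 1e-12)  # 2 + 2 sin(3 pi/2)
  expect_equal(th2(7), 0, tolerance = 1e-12)
  expect_equal(th2(1), 4)
  th1 <- theta_function("case1")
  expect_equal(th1(6), 4)                     # 2 + 2 sin(pi/2)
  expect_gt(min(th1(1:9)), 2)                 # never off in case one
})

test_that("alternative phenotypes add the planted effect on the causal set only", {
  cfg <- scenario_config(n = 400, L = 12, region_class = "common",
                         c = 5, causal_prop = 0.2, theta = "case2",
                         seed = 29)
  geno <- simulate_genotypes_le(cfg)
  eff <- make_effect(cfg, geno)
  sim <- simulate_alt_phenotypes(cfg, geno, eff)
  A <- eff$causal_indices
  expect_equal(sim$beta_true[-A, ], matrix(0, 12 - length(A), 9))
  expect_equal(sim$beta_true[A, 3], rep(0, length(A)))  # gene off
  expect_equal(sim$beta_true[A, 1],
               eff$signs * eff$eta * 4)                  # theta(1) = 4

  # with the effect zeroed the generator reduces to the null model
  eff0 <- eff; eff0$eta <- rep(0, length(eff$eta))
  set.seed(31); sim0 <- simulate_alt_phenotypes(cfg, geno, eff0)
  set.seed(31); ph_null <- simulate_null_phenotypes(cfg, nrow(geno$G))
  expect_equal(sim0$pheno$Y, ph_null$Y)
})

test_that("LD genotypes hit the target adjacent correlation band", {
  cfg <- scenario_config(n = 2000, L = 30, region_class = "common",
                         ld = c(0.25, 0.64), seed = 37)
  g <- simulate_genotypes_ld(cfg)
  r2 <- sapply(seq_len(29), function(l) cor(g$G[, l], g$G[, l + 1])^2)
  expect_gt(mean(r2), 0.25)
  expect_lt(mean(r2), 0.64)
  # margins preserved (binomial 4.5 SE on the allele frequency)
  p_hat <- colMeans(g$G) / 2
  se <- sqrt(g$maf * (1 - g$maf) / (2 * 2000))
  expect_true(all(abs(p_hat - g$maf) < 4.5 * se))
  expect_identical(g$G, simulate_genotypes_ld(cfg)$G)

  # near-zero r2 bounds recover linkage-equilibrium behaviour
  cfg0 <- scenario_config(n = 2000, L = 20, region_class = "common",
                          ld = c(1e-6, 1e-4), seed = 41)
  g0 <- simulate_genotypes_ld(cfg0)
  r20 <- sapply(seq_len(19), function(l) cor(g0$G[, l], g0$G[, l + 1])^2)
  expect_lt(mean(r20), 0.01)
})

test_that("LE genotype columns are uncorrelated on average", {
  cfg <- scenario_config(n = 1000, L = 20, region_class = "common",
                         seed = 43)
  g <- simulate_genotypes_le(cfg)
  C <- cor(g$G)
  pair_r <- C[upper.tri(C)]
  expect_lt(abs(mean(pair_r)), 3 / sqrt(length(pair_r) * 1000))
})
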