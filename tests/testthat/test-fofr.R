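test_that("centering removes the mean curve and is idempotent", {
  d <- toy_dataset(n = 20, effect = 0)
  ph1 <- longitudinal_phenotype(matrix(1, 20, 5), 1:5)
  ctr <- center_data(d$geno, ph1)
  expect_equal(max(abs(ctr$Y_centered)), 0)
  expect_equal(unname(ctr$mean_curve), rep(1, 5))

  Y <- matrix(c(1, 3, 3, 1), 2, 2)
  g2 <- genotype_region(matrix(c(0, 1, 2, 1), 2, 2), c(10, 20),
                        region_length = 30)
  ctr2 <- center_data(g2, longitudinal_phenotype(Y, 1:2))
  expect_equal(unname(ctr2$Y_centered), matrix(c(-1, 1, 1, -1), 2, 2))

  ctr3 <- center_data(d$geno, d$pheno)
  again <- sweep(ctr3$Y_centered, 2L, colMeans(ctr3$Y_centered))
  expect_equal(again, ctr3$Y_centered, tolerance = 1e-12)
  expect_lt(max(abs(colMeans(ctr3$G_centered))), 1e-12)

  g1 <- genotype_region(matrix(1, 1, 2), c(10, 20), region_length = 30)
  expect_error(center_data(g1, longitudinal_phenotype(matrix(1, 1, 5), 1:5)),
               "at least 2 subjects")
})

test_that("the stacked design equals the dense-quadrature definition", {
  set.seed(5)
  n <- 5; L <- 3; m_s <- 4; m_t <- 4
  pos <- c(100, 400, 800)
  sb <- make_bspline_basis(0, 1000, m_s, 4)
  tb <- make_bspline_basis(1, 9, m_t, 4)
  tg <- seq(1, 9, length.out = 6)
  G <- matrix(rbinom(n * L, 2, 0.4), n, L)
  Gc <- sweep(G, 2, colMeans(G))
  W <- genotype_functional_weights(pos, sb)
  Phi <- eval_basis(tb, tg)
  Psi <- build_design(Gc, W, Phi)
  expect_equal(dim(Psi), c(n * 6, m_s * m_t))
  mids <- (pos[-L] + pos[-1]) / 2
  edges <- c(0, mids, 1000)
  s_int <- function(x, j) sum(vapply(seq_len(L), function(l)
    x[l] * trapz_quad(function(s) eval_basis(sb, s)[, j],
                      edges[l], edges[l + 1], n = 4000L), 0))
  for (i in c(1, 3, 5)) {
    for (q in c(1, 4)) for (j in 1:m_s) for (k in 1:m_t) {
      oracle <- s_int(Gc[i, ], j) * Phi[q, k]
      expect_equal(Psi[(i - 1) * 6 + q, (j - 1) * m_t + k], oracle,
                   tolerance = 1e-6 * max(1, abs(oracle)))
    }
  }
  expect_error(build_design(Gc[1, , drop = FALSE], W, Phi), "degenerate")
})

test_that("penalty matrices annihilate linear surfaces, are PSD, and match dense integration", {
  sb <- make_bspline_basis(0, 10, 6, 4)
  tb <- make_bspline_basis(0, 8, 5, 4)
  pen <- build_penalties(sb, tb)

  # coefficients of a function linear in s: values at Greville abscissae
  grev <- sapply(seq_len(6), function(j)
    mean(sb$knots[(j + 1):(j + 3)]))
  C_lin <- outer(1.5 + 2 * grev, rep(1, 5))
  b_lin <- as.vector(t(C_lin))
  expect_lt(abs(drop(b_lin %*% pen$R1 %*% b_lin)), 1e-10)

  grev_t <- sapply(seq_len(5), function(k)
    mean(tb$knots[(k + 1):(k + 3)]))
  C_lin_t <- outer(rep(1, 6), -0.3 + 0.7 * grev_t)
  b_lin_t <- as.vector(t(C_lin_t))
  expect_lt(abs(drop(b_lin_t %*% pen$R2 %*% b_lin_t)), 1e-10)

  expect_gt(min(eigen(pen$R1, symmetric = TRUE)$values), -1e-10)
  expect_gt(min(eigen(pen$R2, symmetric = TRUE)$values), -1e-10)

  set.seed(13)
  C <- matrix(rnorm(30), 6, 5)
  b <- as.vector(t(C))
  s_grid <- seq(0, 10, length.out = 2001)
  t_grid <- seq(0, 8, length.out = 2001)
  d2s <- eval_basis(sb, s_grid, deriv = 2L) %*% C %*%
    t(eval_basis(tb, t_grid))
  oracle1 <- simpson2(d2s^2, s_grid, t_grid)
  expect_equal(drop(b %*% pen$R1 %*% b), oracle1,
               tolerance = 1e-6)
  d2t <- eval_basis(sb, s_grid) %*% C %*%
    t(eval_basis(tb, t_grid, deriv = 2L))
  oracle2 <- simpson2(d2t^2, s_grid, t_grid)
  expect_equal(drop(b %*% pen$R2 %*% b), oracle2,
               tolerance = 1e-6)

  expect_error(build_penalties(make_bspline_basis(0, 1, 2, 2), tb),
               "order")
})

test_that("penalized solve matches the direct inverse and honors limits", {
  set.seed(17)
  n_rows <- 20; K <- 6
  Psi <- matrix(rnorm(n_rows * K), n_rows, K)
  R1 <- crossprod(matrix(rnorm(K * K), K)); R2 <- diag(K)
  y <- rnorm(n_rows)

  b <- penalized_solve(Psi, y, R1, R2, 3, 0.5)
  direct <- solve(crossprod(Psi) + 3 * R1 + 0.5 * R2, crossprod(Psi, y))
  expect_equal(b, as.vector(direct), tolerance = 1e-8)

  expect_equal(penalized_solve(Psi, rep(0, n_rows), R1, R2, 1, 1),
               rep(0, K))

  # normal-equation residual invariant
  A <- crossprod(Psi) + 3 * R1 + 0.5 * R2
  expect_lt(sqrt(sum((A %*% b - crossprod(Psi, y))^2)) /
              sqrt(sum(crossprod(Psi, y)^2)), 1e-8)
})

test_that("curvature shrinks monotonically along an increasing lambda path", {
  d <- toy_dataset(n = 50, L = 8, nq = 7, seed = 23)
  pen_form <- function(fit) {
    b <- surface_coef_vector(fit$surface)
    pen <- fit$penalties
    drop(b %*% pen$R1 %*% b) + drop(b %*% pen$R2 %*% b)
  }
  lams <- c(1e2, 1e5, 1e8, 1e12)
  curv <- rss <- numeric(length(lams))
  for (i in seq_along(lams)) {
    f <- fofr_fit(d$geno, d$pheno, m_s = 5, m_t = 5,
                  lambda1 = lams[i], lambda2 = lams[i])
    curv[i] <- pen_form(f)
    rss[i] <- sum(f$rss1_by_time)
  }
  expect_true(all(diff(curv) <= 1e-10))
  expect_true(all(diff(rss) >= -1e-8))  # training RSS nondecreasing
  expect_lt(curv[length(lams)], 1e-6 * max(curv[1], 1e-12))
})

test_that("block-hat LOOCV equals the explicit refit oracle", {
  d <- toy_dataset(n = 10, L = 6, nq = 4, seed = 31, effect = 0.4)
  ctr <- center_data(d$geno, d$pheno)
  sb <- make_bspline_basis(0, d$geno$region_length, 5, 4)
  tb <- make_bspline_basis(1, 4, 4, 4)
  W <- genotype_functional_weights(d$geno$positions, sb)
  Phi <- eval_basis(tb, d$pheno$time_grid)
  pen <- build_penalties(sb, tb)
  Z <- ctr$G_centered %*% W
  grid <- c(1e2, 1e4)
  hat <- loocv_select(Z, ctr$Y_centered, Phi, pen, grid, method = "hat")
  refit <- loocv_select(Z, ctr$Y_centered, Phi, pen, grid,
                        method = "refit")
  expect_equal(hat$cv_table$cv, refit$cv_table$cv, tolerance = 1e-8)
  expect_equal(hat$lambda1, refit$lambda1)
  expect_equal(nrow(hat$cv_table), 4L)

  single <- loocv_select(Z, ctr$Y_centered, Phi, pen, 500, method = "hat")
  expect_equal(single$lambda1, 500)
  expect_equal(nrow(single$cv_table), 1L)
  expect_error(loocv_select(Z[1:2, ], ctr$Y_centered[1:2, ], Phi, pen,
                            grid), "at least 3")
})

test_that("the default cross-validation grid has 25 candidate pairs", {
  d <- toy_dataset(n = 25, L = 6, nq = 4, seed = 37)
  f <- fofr_fit(d$geno, d$pheno, m_s = 4, m_t = 4)
  expect_equal(nrow(f$cv_table), 25L)
  expect_true(f$lambda1 %in% 10^(2:6) && f$lambda2 %in% 10^(2:6))
})

test_that("fits are deterministic and additive shifts only move the mean curve", {
  d <- toy_dataset(n = 40, L = 8, nq = 5, seed = 41)
  f1 <- fofr_fit(d$geno, d$pheno, m_s = 5, m_t = 4)
  f2 <- fofr_fit(d$geno, d$pheno, m_s = 5, m_t = 4,
                 lambda1 = f1$lambda1, lambda2 = f1$lambda2)
  expect_identical(surface_coef_vector(f1$surface),
                   surface_coef_vector(f2$surface))

  shifted <- longitudinal_phenotype(d$pheno$Y + 3.25, d$pheno$time_grid)
  f3 <- fofr_fit(d$geno, shifted, m_s = 5, m_t = 4,
                 lambda1 = f1$lambda1, lambda2 = f1$lambda2)
  expect_equal(f3$mean_curve, f1$mean_curve + 3.25)
  expect_equal(f3$fitted, f1$fitted, tolerance = 1e-9)
  expect_equal(surface_coef_vector(f3$surface),
               surface_coef_vector(f1$surface), tolerance = 1e-9)

  # fitted + residuals reconstruct the centered phenotypes exactly
  ctr <- center_data(d$geno, d$pheno)
  expect_equal(f1$fitted + f1$residuals, ctr$Y_centered)
  expect_equal(f1$rss1_by_time, colSums(f1$residuals^2))
})

test_that("prediction reproduces in-sample fits and the mean-genotype curve", {
  d <- toy_dataset(n = 40, L = 8, nq = 5, seed = 43)
  f <- fofr_fit(d$geno, d$pheno, m_s = 5, m_t = 4,
                lambda1 = 1e3, lambda2 = 1e3)
  pred <- predict(f, d$geno)
  expect_equal(pred, sweep(f$fitted, 2, f$mean_curve, `+`),
               tolerance = 1e-10)

  g_mean <- genotype_region(rbind(f$x_mean, f$x_mean), d$geno$positions,
                            region_length = d$geno$region_length)
  expect_equal(unname(predict(f, g_mean)[1, ]), unname(f$mean_curve),
               tolerance = 1e-10)

  g_bad <- genotype_region(d$geno$G, d$geno$positions + 1,
                           region_length = d$geno$region_length + 2)
  expect_error(predict(f, g_bad), "positions")
})

test_that("prediction equals dense quadrature of the fitted surface", {
  d <- toy_dataset(n = 30, L = 6, nq = 5, seed = 47)
  f <- fofr_fit(d$geno, d$pheno, m_s = 5, m_t = 4,
                lambda1 = 1e3, lambda2 = 1e3)
  i <- 4
  xc <- d$geno$G[i, ] - f$x_mean
  pos <- d$geno$positions; L <- length(pos); M <- d$geno$region_length
  edges <- c(0, (pos[-L] + pos[-1]) / 2, M)
  pred <- predict(f, d$geno)
  for (q in c(1, 3, 5)) {
    tq <- d$pheno$time_grid[q]
    oracle <- f$mean_curve[q] + sum(vapply(seq_len(L), function(l)
      xc[l] * trapz_quad(function(s)
        as.vector(eval_surface(f$surface, s, tq)),
        edges[l], edges[l + 1], n = 3000L), 0))
    expect_equal(unname(pred[i, q]), unname(oracle), tolerance = 1e-5)
  }
})

test_that("under the null the per-time p-values are conservative", {
  set.seed(53)
  nrep <- 120; n <- 120
  cfg <- scenario_config(n = n, L = 10, region_class = "common")
  hits <- 0; total <- 0
  for (r in seq_len(nrep)) {
    geno <- simulate_genotypes_le(cfg)
    pheno <- simulate_null_phenotypes(cfg)
    f <- fofr_fit(geno, pheno, m_s = 5, m_t = 5,
                  lambda1 = 1e2, lambda2 = 1e2)
    p <- f_test_all(f)$p_by_time
    hits <- hits + sum(p < 0.05)
    total <- total + length(p)
  }
  # rejection rate must not exceed nominal (3 binomial SEs of slack)
  expect_lt(hits / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})
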