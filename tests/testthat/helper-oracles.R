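# Shared oracles and small-data builders for the test suite.

# dense trapezoid quadrature of f (vectorized) on [a, b]
trapz_quad <- function(f, a, b, n = 10000L) {
  x <- seq(a, b, length.out = n)
  y <- f(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

# 2-D trapezoid integration of a matrix of values V[i, q] on the grid
# s_grid x t_grid
trapz2 <- function(V, s_grid, t_grid) {
  ws <- diff(s_grid); wt <- diff(t_grid)
  col_int <- colSums((V[-1, , drop = FALSE] +
                        V[-nrow(V), , drop = FALSE]) / 2 * ws)
  sum((col_int[-1] + col_int[-length(col_int)]) / 2 * wt)
}

# composite Simpson weights for an odd number of uniform grid points
simpson_weights <- function(grid) {
  n <- length(grid)
  stopifnot(n %% 2 == 1)
  h <- (grid[n] - grid[1]) / (n - 1)
  w <- rep(2, n); w[seq(2, n - 1, by = 2)] <- 4; w[c(1, n)] <- 1
  w * h / 3
}

# 2-D composite Simpson integration of V[i, q] on uniform grids
simpson2 <- function(V, s_grid, t_grid) {
  drop(simpson_weights(s_grid) %*% V %*% simpson_weights(t_grid))
}

# step-function genotype profile: value x[l] between the midpoints
# flanking SNP l (clipped to [lo, hi])
step_profile <- function(x, positions, lo, hi) {
  L <- length(positions)
  edges <- c(lo, if (L > 1) (positions[-L] + positions[-1]) / 2, hi)
  function(s) x[findInterval(s, edges, rightmost.closed = TRUE)]
}

# brute-force tensor surface evaluation by the explicit double sum
surface_double_sum <- function(surface, s, t) {
  Es <- eval_basis(surface$s_basis, s)
  Et <- eval_basis(surface$t_basis, t)
  total <- 0
  for (j in seq_len(surface$s_basis$n_basis))
    for (k in seq_len(surface$t_basis$n_basis))
      total <- total + surface$coef[j, k] * Es[1, j] * Et[1, k]
  total
}

# small matched genotype/phenotype pair with a planted effect
toy_dataset <- function(n = 60, L = 8, nq = 5, seed = 42,
                        effect = 0.6, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(L, 0.1, 0.5)
  G <- matrix(rbinom(n * L, 2, rep(maf, each = n)), n, L)
  geno <- genotype_region(G, (seq_len(L) - 0.5) * 1000 / L,
                          region_length = 1000, maf = maf)
  tg <- seq_len(nq)
  Y <- 1 + matrix(rnorm(n * nq), n, nq)
  if (effect != 0) Y <- Y + outer(G[, 1] * effect, 1 + tg / nq)
  list(geno = geno, pheno = longitudinal_phenotype(Y, tg))
}
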