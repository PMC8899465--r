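# Single-time-point comparator: scalar-on-function regression of one
# measurement on the genotype function, with a curvature ridge penalty in
# the position direction and an F test.  Applied per time point, this is
# the smoothed functional linear model baseline against which the
# longitudinal test is contrasted.

# core fit on precomputed ingredients; leave-one-out CV via the ridge hat
# diagonal, ties to the larger (smoother) lambda
.flm_core <- function(Z, y, Ps, lambda_grid) {
  n <- nrow(Z); m_s <- ncol(Z)
  yc <- y - mean(y)
  ZtZ <- crossprod(Z); Zty <- crossprod(Z, yc)
  best <- NULL
  for (lam in sort(lambda_grid)) {
    M <- ZtZ + lam * Ps
    Ai <- tryCatch(chol2inv(chol(M)), error = function(e) NULL)
    if (is.null(Ai)) {  # rank-deficient (e.g. monomorphic region): jitter
      jit <- 1e-10 * max(sum(diag(M)) / nrow(M), 1)
      Ai <- tryCatch(chol2inv(chol(M + diag(jit, nrow(M)))),
                     error = function(e) NULL)
    }
    if (is.null(Ai)) next
    bh <- Ai %*% Zty
    fit <- as.vector(Z %*% bh)
    h <- rowSums((Z %*% Ai) * Z)
    cv <- mean(((yc - fit) / (1 - h))^2)
    if (is.null(best) || cv < best$cv - 1e-12 ||
        (abs(cv - best$cv) <= 1e-12 && lam > best$lambda))
      best <- list(cv = cv, lambda = lam, coef = as.vector(bh), fit = fit)
  }
  if (is.null(best))
    stop("smoothed FLM system singular at every lambda in the grid")
  rss0 <- sum(yc^2); rss1 <- sum((yc - best$fit)^2)
  Fv <- max(0, (rss0 - rss1) / m_s) / (rss1 / (n - m_s - 1))
  list(coef = best$coef, lambda = best$lambda, rss0 = rss0, rss1 = rss1,
       f = Fv, p = stats::pf(Fv, m_s, n - m_s - 1, lower.tail = FALSE))
}

#' Smoothed functional linear model test at a single time point
#'
#' Regresses one time point's centered phenotype on the genotype-basis
#' integrals \code{Z = Gc W} (the same position-direction functional
#' weights the longitudinal test uses), with ridge penalty
#' \code{lambda * P_s} (integrated squared second derivative in s) and
#' \code{lambda} chosen by leave-one-out cross-validation.  The F
#' statistic uses \code{(m_s, n - m_s - 1)} degrees of freedom.
#'
#' @param geno an \code{"lfdat_genotypes"} object.
#' @param y_t numeric vector: the phenotype at one time point.
#' @param m_s position-basis dimension.
#' @param order spline order.
#' @param lambda_grid candidate smoothing values.
#' @param weights_mode genotype-function convention, see
#'   \code{\link{genotype_functional_weights}}.
#' @return an object of class \code{"lfdat_flm"} with \code{s_basis},
#'   \code{coef}, \code{lambda}, \code{rss0}, \code{rss1}, \code{f},
#'   \code{p}.
#' @export
smoothed_flm_test <- function(geno, y_t, m_s = 15L, order = 4L,
                              lambda_grid = 10^(2:6),
                              weights_mode = c("step", "point")) {
  stopifnot(inherits(geno, "lfdat_genotypes"))
  weights_mode <- match.arg(weights_mode)
  n <- nrow(geno$G)
  if (length(y_t) != n) stop("y_t must have one value per subject")
  if (n <= m_s + 1L)
    stop("degrees of freedom exhausted: need n > m_s + 1")
  s_basis <- make_bspline_basis(0, geno$region_length, m_s, order)
  W <- genotype_functional_weights(geno$positions, s_basis, weights_mode)
  Z <- sweep(geno$G, 2L, colMeans(geno$G)) %*% W
  core <- .flm_core(Z, y_t, basis_gram(s_basis, 2L), lambda_grid)
  structure(c(list(s_basis = s_basis), core), class = "lfdat_flm")
}

#' @export
print.lfdat_flm <- function(x, ...) {
  cat("Smoothed FLM test: F =", signif(x$f, 4), " p =", signif(x$p, 4),
      " (lambda =", format(x$lambda), ")\n")
  invisible(x)
}
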