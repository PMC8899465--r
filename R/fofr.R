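# Penalized function-on-function regression: centering, tensor design,
# two-directional roughness penalties, penalized normal equations, and
# leave-one-subject-out cross-validation for the smoothing parameters.
#
# The stacked design never needs to be formed for fitting: with the
# tensor-product basis the cross-product factorizes as
#   Psi' Psi = (Z'Z) x (Phi'Phi),   Psi' y = vec_rowmajor(Z' Y Phi),
# where Z = Gc W holds the genotype-basis integrals and Phi the time-basis
# values on the measurement grid.  All heavy computation is done in this
# K x K Kronecker form; build_design() materializes Psi for small problems
# and for verification.

#' Center genotypes and phenotypes
#'
#' Subtracts the per-time-point phenotype mean curve and the per-SNP mean
#' genotype, the standard reduction that removes the population mean curve
#' from the regression.
#'
#' @param geno an \code{"lfdat_genotypes"} object.
#' @param pheno a matched \code{"lfdat_phenotypes"} object.
#' @return list with \code{G_centered}, \code{Y_centered},
#'   \code{mean_curve} (phenotype column means) and \code{x_mean}
#'   (genotype column means).
#' @export
center_data <- function(geno, pheno) {
  .check_matched(geno, pheno)
  if (nrow(geno$G) < 2L) stop("need at least 2 subjects to center")
  x_mean <- colMeans(geno$G)
  mean_curve <- colMeans(pheno$Y)
  list(G_centered = sweep(geno$G, 2L, x_mean),
       Y_centered = sweep(pheno$Y, 2L, mean_curve),
       mean_curve = mean_curve, x_mean = x_mean)
}

#' Stacked design matrix of the function-on-function regression
#'
#' Materializes the \code{n(Q+1) x K} design whose row for subject
#' \code{i} at time index \code{q} is the Kronecker product of the
#' genotype-basis integrals \code{(Gc W)[i, ]} with the time-basis values
#' \code{Phi[q, ]}.  Rows are ordered subject-major, time-minor; columns
#' follow the row-major (position-major) flattening of the coefficient
#' surface.
#'
#' @param G_centered centered genotype matrix (subjects x SNPs).
#' @param weights genotype functional weights from
#'   \code{\link{genotype_functional_weights}}.
#' @param t_basis_eval time-basis evaluation matrix \code{(Q+1) x m_t}.
#' @return numeric matrix \code{n(Q+1) x (m_s m_t)}.
#' @export
build_design <- function(G_centered, weights, t_basis_eval) {
  G_centered <- as.matrix(G_centered)
  if (nrow(G_centered) < 2L)
    stop("design degenerate: need at least 2 subjects")
  if (ncol(G_centered) != nrow(weights))
    stop("weights must have one row per SNP")
  Z <- G_centered %*% weights
  Phi <- as.matrix(t_basis_eval)
  n <- nrow(Z); m_s <- ncol(Z); nq <- nrow(Phi); m_t <- ncol(Phi)
  Z[rep(seq_len(n), each = nq), rep(seq_len(m_s), each = m_t)] *
    Phi[rep(seq_len(nq), times = n), rep(seq_len(m_t), times = m_s)]
}

#' Two-directional roughness penalty matrices
#'
#' For the tensor-product surface, the integrated squared second
#' derivative in the position direction has quadratic form
#' \code{b' R1 b} with \code{R1 = P_s x M_t} (Kronecker product of the
#' curvature Gram in s and the plain Gram in t); the time-direction
#' penalty is \code{R2 = M_s x P_t}.
#'
#' @param s_basis,t_basis marginal \code{"lfdat_basis"} objects with
#'   \code{order >= 3} (second derivatives must exist).
#' @return an object of class \code{"lfdat_penalties"} with elements
#'   \code{R1}, \code{R2} (both \code{K x K}, symmetric PSD) and the
#'   marginal factors \code{Ms}, \code{Mt}, \code{Ps}, \code{Pt}.
#' @export
build_penalties <- function(s_basis, t_basis) {
  if (s_basis$order < 3L || t_basis$order < 3L)
    stop("penalties require spline order >= 3")
  Ms <- basis_gram(s_basis, 0L); Ps <- basis_gram(s_basis, 2L)
  Mt <- basis_gram(t_basis, 0L); Pt <- basis_gram(t_basis, 2L)
  structure(list(R1 = kronecker(Ps, Mt), R2 = kronecker(Ms, Pt),
                 Ms = Ms, Mt = Mt, Ps = Ps, Pt = Pt),
            class = "lfdat_penalties")
}

# symmetric PD solve with a one-shot trace jitter fallback
.pd_solve <- function(A, rhs) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    jitter <- 1e-10 * sum(diag(A)) / nrow(A)
    ch <- tryCatch(chol(A + diag(jitter, nrow(A))), error = function(e) NULL)
    if (is.null(ch))
      stop("penalized system is singular: increase lambda1/lambda2 or ",
           "reduce the basis dimensions (m_s, m_t)")
    attr(ch, "jittered") <- TRUE
  }
  backsolve(ch, forwardsolve(t(ch), rhs))
}

#' Solve the penalized normal equations
#'
#' Computes the minimizer of the penalized sum of squares,
#' \code{b = (Psi'Psi + lambda1 R1 + lambda2 R2)^{-1} Psi'y}.
#'
#' @param Psi stacked design matrix (see \code{\link{build_design}}).
#' @param y stacked response vector (subject-major, time-minor).
#' @param R1,R2 penalty matrices from \code{\link{build_penalties}}.
#' @param lambda1,lambda2 nonnegative smoothing parameters.
#' @return coefficient vector of length \code{ncol(Psi)}.
#' @export
penalized_solve <- function(Psi, y, R1, R2, lambda1, lambda2) {
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  A <- crossprod(Psi) + lambda1 * R1 + lambda2 * R2
  as.vector(.pd_solve(A, crossprod(Psi, y)))
}

# Kronecker-form fit: returns coefficient matrix B (m_s x m_t), fitted
# values Z B Phi', and the system matrix pieces for reuse.
.fit_kron <- function(Z, Yc, Phi, pen, lambda1, lambda2) {
  A <- kronecker(crossprod(Z), crossprod(Phi)) +
    lambda1 * pen$R1 + lambda2 * pen$R2
  rhs <- as.vector(t(crossprod(Z, Yc %*% Phi)))
  b <- as.vector(.pd_solve(A, rhs))
  B <- matrix(b, ncol(Z), ncol(Phi), byrow = TRUE)
  list(b = b, B = B, fitted = Z %*% B %*% t(Phi), A = A, rhs = rhs)
}

#' Leave-one-subject-out selection of the smoothing parameters
#'
#' Evaluates every pair on the Cartesian grid and returns the pair
#' minimizing the leave-one-subject-out prediction error.  Because the
#' penalized fit is a linear smoother, deleting all rows of one subject
#' admits the exact block hat-matrix identity
#' \code{e_cv_i = (I - H_ii)^{-1} e_i}; \code{method = "refit"} instead
#' refits without each subject (slow; kept as a verification path).
#' Ties go to the smoother pair (larger \code{lambda1 + lambda2}, then
#' larger \code{lambda2}).
#'
#' @param Z genotype-basis integral matrix (n x m_s), centered.
#' @param Yc centered phenotype matrix (n x (Q+1)).
#' @param Phi time-basis evaluation matrix ((Q+1) x m_t).
#' @param penalties an \code{"lfdat_penalties"} object.
#' @param lambda_grid candidate values; the grid is the Cartesian product
#'   of this vector with itself for \code{(lambda1, lambda2)}.
#' @param method \code{"hat"} (block hat-matrix identity) or
#'   \code{"refit"} (explicit per-subject refit).
#' @return list with \code{lambda1}, \code{lambda2} and \code{cv_table}
#'   (one row per candidate pair with its CV mean squared error).
#' @export
loocv_select <- function(Z, Yc, Phi, penalties,
                         lambda_grid = 10^(2:6),
                         method = c("hat", "refit")) {
  method <- match.arg(method)
  if (length(lambda_grid) < 1L) stop("empty lambda grid")
  n <- nrow(Z)
  if (n < 3L) stop("leave-one-subject-out needs at least 3 subjects")
  nq <- nrow(Phi); m_s <- ncol(Z); m_t <- ncol(Phi)
  grid <- expand.grid(lambda1 = lambda_grid, lambda2 = lambda_grid)
  cv <- numeric(nrow(grid))
  if (method == "hat") {
    # rows of ZZ hold vec(z_i z_i') (column-major), so that the subject
    # block of the hat matrix contracts to H_ii = Phi T_i Phi' with
    # vec(T_i) = ZZ[i, ] %*% Cmat
    ZZ <- Z[, rep(seq_len(m_s), times = m_s)] *
      Z[, rep(seq_len(m_s), each = m_s)]
    for (g in seq_len(nrow(grid))) {
      f <- .fit_kron(Z, Yc, Phi, penalties, grid$lambda1[g], grid$lambda2[g])
      Cinv <- chol2inv(chol(f$A))
      C4 <- array(Cinv, dim = c(m_t, m_s, m_t, m_s))
      Cmat <- matrix(aperm(C4, c(2, 4, 1, 3)), m_s * m_s, m_t * m_t)
      TT <- ZZ %*% Cmat
      E <- Yc - f$fitted
      acc <- 0
      I_q <- diag(nq)
      for (i in seq_len(n)) {
        Ti <- matrix(TT[i, ], m_t, m_t)
        H_ii <- Phi %*% Ti %*% t(Phi)
        acc <- acc + sum(solve(I_q - H_ii, E[i, ])^2)
      }
      cv[g] <- acc / (n * nq)
    }
  } else {
    for (g in seq_len(nrow(grid))) {
      acc <- 0
      for (i in seq_len(n)) {
        f <- .fit_kron(Z[-i, , drop = FALSE], Yc[-i, , drop = FALSE], Phi,
                       penalties, grid$lambda1[g], grid$lambda2[g])
        pred <- as.vector(Z[i, ] %*% f$B %*% t(Phi))
        acc <- acc + sum((Yc[i, ] - pred)^2)
      }
      cv[g] <- acc / (n * nq)
    }
  }
  # smoother pair wins ties (then larger lambda2, deterministically)
  ord <- order(cv, -(grid$lambda1 + grid$lambda2), -grid$lambda2)
  best <- ord[1L]
  list(lambda1 = grid$lambda1[best], lambda2 = grid$lambda2[best],
       cv_table = cbind(grid, cv = cv))
}

#' Fit the penalized function-on-function regression
#'
#' End-to-end fit: centers the data, builds the genotype functional
#' weights and the tensor design, assembles the two roughness penalties,
#' optionally selects the smoothing parameters by leave-one-subject-out
#' cross-validation, and solves the penalized normal equations.
#'
#' The position basis lives on \code{[0, region_length]} in physical
#' coordinates and the time basis on the raw measurement interval, so the
#' smoothing-parameter grid acts on the same scales throughout.
#'
#' @param geno an \code{"lfdat_genotypes"} object.
#' @param pheno a matched \code{"lfdat_phenotypes"} object.
#' @param m_s,m_t marginal B-spline basis dimensions (the coefficient
#'   count is \code{K = m_s * m_t}).
#' @param order spline order for both directions (4 = cubic).
#' @param lambda1,lambda2 smoothing parameters; when either is
#'   \code{NULL} both are selected by \code{\link{loocv_select}} over
#'   \code{lambda_grid}.
#' @param lambda_grid candidate smoothing values for cross-validation.
#' @param weights_mode genotype-function convention, see
#'   \code{\link{genotype_functional_weights}}.
#' @param cv_method passed to \code{\link{loocv_select}}.
#' @return an object of class \code{"lfdat_fofr"} with the fitted
#'   coefficient \code{surface}, \code{mean_curve}, \code{x_mean},
#'   \code{lambda1}, \code{lambda2}, centered \code{fitted} values and
#'   \code{residuals}, per-time residual sums of squares
#'   \code{rss0_by_time} / \code{rss1_by_time}, the coefficient count
#'   \code{K}, and the design ingredients needed for prediction.
#' @export
fofr_fit <- function(geno, pheno, m_s = 15L, m_t = 15L, order = 4L,
                     lambda1 = NULL, lambda2 = NULL,
                     lambda_grid = 10^(2:6),
                     weights_mode = c("step", "point"),
                     cv_method = c("hat", "refit")) {
  weights_mode <- match.arg(weights_mode)
  cv_method <- match.arg(cv_method)
  .check_matched(geno, pheno)
  ctr <- center_data(geno, pheno)
  s_basis <- make_bspline_basis(0, geno$region_length, m_s, order)
  tg <- pheno$time_grid
  t_basis <- make_bspline_basis(tg[1L], tg[length(tg)], m_t, order)
  W <- genotype_functional_weights(geno$positions, s_basis, weights_mode)
  Phi <- eval_basis(t_basis, tg)
  pen <- build_penalties(s_basis, t_basis)
  Z <- ctr$G_centered %*% W
  cv_table <- NULL
  if (is.null(lambda1) || is.null(lambda2)) {
    sel <- loocv_select(Z, ctr$Y_centered, Phi, pen, lambda_grid, cv_method)
    lambda1 <- sel$lambda1; lambda2 <- sel$lambda2
    cv_table <- sel$cv_table
  }
  f <- .fit_kron(Z, ctr$Y_centered, Phi, pen, lambda1, lambda2)
  resid <- ctr$Y_centered - f$fitted
  structure(list(
    surface = surface_from_vector(s_basis, t_basis, f$b),
    mean_curve = ctr$mean_curve, x_mean = ctr$x_mean,
    lambda1 = lambda1, lambda2 = lambda2,
    fitted = f$fitted, residuals = resid,
    rss0_by_time = colSums(ctr$Y_centered^2),
    rss1_by_time = colSums(resid^2),
    K = m_s * m_t, n = nrow(geno$G),
    time_grid = tg, positions = geno$positions,
    weights = W, weights_mode = weights_mode,
    Phi = Phi, penalties = pen, cv_table = cv_table),
    class = "lfdat_fofr")
}

#' Predict phenotype curves for new subjects
#'
#' @param object an \code{"lfdat_fofr"} fit.
#' @param geno_new an \code{"lfdat_genotypes"} object with positions
#'   identical to the training region.
#' @param ... unused.
#' @return matrix of predicted trait values, new subjects x time points
#'   (training mean curve plus the centered genetic effect).
#' @export
predict.lfdat_fofr <- function(object, geno_new, ...) {
  stopifnot(inherits(geno_new, "lfdat_genotypes"))
  if (length(geno_new$positions) != length(object$positions) ||
      any(geno_new$positions != object$positions))
    stop("new genotypes must be on the training SNP positions")
  Gc <- sweep(geno_new$G, 2L, object$x_mean)
  B <- object$surface$coef
  eff <- (Gc %*% object$weights) %*% B %*% t(object$Phi)
  sweep(eff, 2L, object$mean_curve, `+`)
}

#' @export
print.lfdat_fofr <- function(x, ...) {
  cat("Function-on-function regression fit\n")
  cat("  subjects:", x$n, "  SNPs:", length(x$positions),
      "  time points:", length(x$time_grid), "\n")
  cat("  K =", x$K, "coefficients;  lambda1 =", format(x$lambda1),
      " lambda2 =", format(x$lambda2), "\n")
  invisible(x)
}
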