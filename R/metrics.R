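# Fit-quality metrics for simulation studies: integrated squared error of
# the estimated effect surface over the null-effect grid (ISE0) and the
# causal grid (ISE1), and prediction mean squared error on held-out
# subjects (PMSE).  Denominators follow the discrete definitions used in
# the simulation tables: (|Gamma|-1)(|S|-1) for the ISE metrics and N-1
# for PMSE (not plain means).

.ise <- function(beta_true, beta_hat, label) {
  beta_true <- as.matrix(beta_true); beta_hat <- as.matrix(beta_hat)
  if (!all(dim(beta_true) == dim(beta_hat)))
    stop("beta_true and beta_hat must have identical dimensions")
  nS <- nrow(beta_true); nT <- ncol(beta_true)
  if (nS < 2L || nT < 2L)
    stop("ISE denominator undefined: need at least 2 sites in ", label,
         " and 2 time points (got |", label, "| = ", nS,
         ", |Gamma| = ", nT, ")")
  sum((beta_hat - beta_true)^2) / ((nT - 1) * (nS - 1))
}

#' Integrated squared error over the null-effect grid (ISE0)
#'
#' Sum of squared deviations between the true and estimated effect at the
#' SNP-by-time grid cells where the true effect is zero, divided by
#' \code{(|Gamma| - 1)(|S0| - 1)}.
#'
#' @param beta_true,beta_hat matrices over the null sites S0 (rows) and
#'   the time grid (columns).
#' @return nonnegative scalar; 0 iff exact agreement.
#' @export
ise_null <- function(beta_true, beta_hat) .ise(beta_true, beta_hat, "S0")

#' Integrated squared error over the causal grid (ISE1)
#'
#' As \code{\link{ise_null}} but over the sites with nonzero true effect;
#' requires at least two causal sites for the \code{|S1| - 1} denominator.
#'
#' @inheritParams ise_null
#' @return nonnegative scalar.
#' @export
ise_nonnull <- function(beta_true, beta_hat) .ise(beta_true, beta_hat, "S1")

#' Prediction mean squared error on a test set
#'
#' Predicts the phenotype curves of held-out subjects from their genotypes
#' and the fitted model, and returns
#' \code{sum of squared prediction errors / (N - 1)} where \code{N} is the
#' number of test subjects.
#'
#' @param fit an \code{"lfdat_fofr"} fit.
#' @param test_geno an \code{"lfdat_genotypes"} object on the training SNP
#'   positions (subjects disjoint from training).
#' @param test_pheno the matched \code{"lfdat_phenotypes"} object.
#' @return nonnegative scalar.
#' @export
pmse <- function(fit, test_geno, test_pheno) {
  stopifnot(inherits(fit, "lfdat_fofr"))
  .check_matched(test_geno, test_pheno)
  N <- nrow(test_pheno$Y)
  if (N < 2L) stop("PMSE denominator undefined: need at least 2 test subjects")
  pred <- predict(fit, test_geno)
  sum((test_pheno$Y - pred)^2) / (N - 1)
}
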