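# Scenario runners: replicate-level type-I error, power, and
# surface-recovery metric studies.  Each replicate draws a fresh gene
# region and phenotype set; every replicate's seed derives from the
# master seed, so whole experiments are bit-reproducible.
#
# The faithful mode reselects the smoothing parameters by
# leave-one-subject-out cross-validation in every replicate; the default
# fast mode selects them once on the first replicate and holds them fixed
# (recorded in the result metadata).

.replicate_seeds <- function(seed, n_reps) {
  if (!is.null(seed)) set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_reps)
}

.sim_geno <- function(config) {
  if (is.null(config$ld)) simulate_genotypes_le(config)
  else simulate_genotypes_ld(config)
}

.subset_geno <- function(geno, idx)
  genotype_region(geno$G[idx, , drop = FALSE], geno$positions,
                  region_length = geno$region_length,
                  subject_ids = geno$subject_ids[idx],
                  snp_ids = geno$snp_ids, maf = geno$maf)

.subset_pheno <- function(pheno, idx)
  longitudinal_phenotype(pheno$Y[idx, , drop = FALSE], pheno$time_grid,
                         subject_ids = pheno$subject_ids[idx])

# shared replicate loop for the rejection-rate experiments
.run_rejection <- function(config, n_reps, alphas, null_model,
                           m_s, m_t, order, lambda_grid, fixed_lambda,
                           include_flm, seed) {
  stopifnot(inherits(config, "lfdat_scenario"), n_reps >= 1L)
  t0 <- proc.time()[["elapsed"]]
  seeds <- .replicate_seeds(seed %||% config$seed, n_reps)
  nq <- length(config$time_grid)
  p_lfdat <- matrix(NA_real_, n_reps, nq)
  p_flm <- if (include_flm) matrix(NA_real_, n_reps, nq) else NULL
  lam <- NULL
  flm_sb <- make_bspline_basis(0, config$region_length, m_s, order)
  flm_Ps <- basis_gram(flm_sb, 2L)
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    geno <- .sim_geno(config)
    pheno <- if (null_model) simulate_null_phenotypes(config) else
      simulate_alt_phenotypes(config, geno,
                              make_effect(config, geno))$pheno
    select_now <- is.null(lam) || !fixed_lambda
    fit <- fofr_fit(geno, pheno, m_s = m_s, m_t = m_t, order = order,
                    lambda1 = if (select_now) NULL else lam[1L],
                    lambda2 = if (select_now) NULL else lam[2L],
                    lambda_grid = lambda_grid)
    if (select_now) lam <- c(fit$lambda1, fit$lambda2)
    p_lfdat[r, ] <- f_test_all(fit, alphas)$p_by_time
    if (include_flm) {
      W <- genotype_functional_weights(geno$positions, flm_sb)
      Z <- sweep(geno$G, 2L, colMeans(geno$G)) %*% W
      p_flm[r, ] <- vapply(seq_len(nq), function(q)
        .flm_core(Z, pheno$Y[, q], flm_Ps, lambda_grid)$p, 0)
    }
  }
  # "<=" so that a (conservative) p rounding to exactly 1 counts as a
  # rejection at alpha = 1; identical to "<" at any interior level
  rates <- lapply(alphas, function(a) colMeans(p_lfdat <= a))
  names(rates) <- as.character(alphas)
  flm_rates <- if (include_flm) {
    fr <- lapply(alphas, function(a) colMeans(p_flm <= a))
    names(fr) <- as.character(alphas)
    fr
  } else NULL
  structure(list(scenario = config, n_reps = n_reps, alphas = alphas,
                 null_model = null_model,
                 rejection_rate_by_time = rates,
                 flm_rejection_rate_by_time = flm_rates,
                 p_by_time = p_lfdat, flm_p_by_time = p_flm,
                 lambda = lam, fixed_lambda = fixed_lambda,
                 seeds = seeds,
                 elapsed_sec = proc.time()[["elapsed"]] - t0),
            class = "lfdat_experiment")
}

#' Type-I error experiment
#'
#' Simulates \code{n_reps} null datasets (fresh genotypes each replicate,
#' phenotypes independent of them) and reports, per significance level and
#' per time point, the fraction of replicates whose per-time p-value falls
#' below the level.
#'
#' @param config an \code{"lfdat_scenario"} (the effect settings are
#'   ignored under the null).
#' @param n_reps number of simulated datasets.
#' @param alphas significance levels.
#' @param m_s,m_t,order,lambda_grid passed to \code{\link{fofr_fit}}.
#' @param fixed_lambda if \code{TRUE} (default) the smoothing parameters
#'   are selected by cross-validation on the first replicate and then held
#'   fixed; \code{FALSE} reselects every replicate.
#' @param include_flm also run the single-time-point smoothed FLM
#'   comparator at every time point.
#' @param seed master seed (defaults to \code{config$seed}).
#' @return an object of class \code{"lfdat_experiment"}; element
#'   \code{rejection_rate_by_time} maps each alpha to a per-time rate
#'   vector.
#' @export
run_type1 <- function(config, n_reps = 1000L,
                      alphas = c(0.05, 0.01, 0.001),
                      m_s = 15L, m_t = 15L, order = 4L,
                      lambda_grid = 10^(2:6), fixed_lambda = TRUE,
                      include_flm = FALSE, seed = NULL) {
  .run_rejection(config, n_reps, alphas, null_model = TRUE,
                 m_s, m_t, order, lambda_grid, fixed_lambda,
                 include_flm, seed)
}

#' Power experiment
#'
#' As \code{\link{run_type1}} but phenotypes carry the scenario's genetic
#' effect; a fresh causal set, MAF draw and sign assignment is made each
#' replicate.  For the gene-switching time effect (\code{theta =
#' "case2"}), the rates at t = 3 and t = 7 estimate the per-time null
#' rate, since the effect is exactly zero there.
#'
#' @inheritParams run_type1
#' @return an object of class \code{"lfdat_experiment"}.
#' @export
run_power <- function(config, n_reps = 1000L,
                      alphas = c(0.05, 0.01, 0.001),
                      m_s = 15L, m_t = 15L, order = 4L,
                      lambda_grid = 10^(2:6), fixed_lambda = TRUE,
                      include_flm = FALSE, seed = NULL) {
  .run_rejection(config, n_reps, alphas, null_model = FALSE,
                 m_s, m_t, order, lambda_grid, fixed_lambda,
                 include_flm, seed)
}

#' Surface-recovery metric experiment
#'
#' Per replicate: simulate genotypes and alternative phenotypes, split
#' subjects into a training and a held-out test set, fit on the training
#' set, then record ISE0 / ISE1 of the recovered effect surface on the
#' SNP-by-time grid and the prediction mean squared error on the test
#' subjects.  Requires at least two causal SNPs (the ISE1 denominator is
#' \code{|S1| - 1}).
#'
#' @inheritParams run_type1
#' @param train_frac fraction of subjects used for fitting (the rest form
#'   the PMSE test set).
#' @param lambda1,lambda2 optional fixed smoothing parameters; when given
#'   they are used in every replicate (no cross-validation), which keeps
#'   matched-seed comparisons across scenarios on the same smoother.
#' @return an object of class \code{"lfdat_experiment"} with
#'   \code{metric_means}, \code{metric_sds} and the per-replicate
#'   \code{metrics} table.
#' @export
run_metrics <- function(config, n_reps = 100L, train_frac = 0.8,
                        m_s = 15L, m_t = 15L, order = 4L,
                        lambda_grid = 10^(2:6), fixed_lambda = TRUE,
                        lambda1 = NULL, lambda2 = NULL, seed = NULL) {
  stopifnot(inherits(config, "lfdat_scenario"), n_reps >= 1L,
            train_frac > 0, train_frac < 1)
  if (max(1L, round(config$causal_prop * config$L)) < 2L)
    stop("metric experiment needs >= 2 causal SNPs for the ISE1 ",
         "denominator; raise causal_prop or L")
  t0 <- proc.time()[["elapsed"]]
  seeds <- .replicate_seeds(seed %||% config$seed, n_reps)
  out <- matrix(NA_real_, n_reps, 3L,
                dimnames = list(NULL, c("ise0", "ise1", "pmse")))
  lam <- if (!is.null(lambda1) && !is.null(lambda2))
    c(lambda1, lambda2) else NULL
  for (r in seq_len(n_reps)) {
    set.seed(seeds[r])
    geno <- .sim_geno(config)
    effect <- make_effect(config, geno)
    sim <- simulate_alt_phenotypes(config, geno, effect)
    n <- config$n
    train <- sort(sample(n, round(train_frac * n)))
    test <- setdiff(seq_len(n), train)
    select_now <- is.null(lam) || !fixed_lambda
    fit <- fofr_fit(.subset_geno(geno, train),
                    .subset_pheno(sim$pheno, train),
                    m_s = m_s, m_t = m_t, order = order,
                    lambda1 = if (select_now) NULL else lam[1L],
                    lambda2 = if (select_now) NULL else lam[2L],
                    lambda_grid = lambda_grid)
    if (select_now) lam <- c(fit$lambda1, fit$lambda2)
    beta_hat <- eval_surface(fit$surface, geno$positions, config$time_grid)
    A <- effect$causal_indices
    S0 <- setdiff(seq_len(config$L), A)
    out[r, "ise0"] <- ise_null(sim$beta_true[S0, , drop = FALSE],
                               beta_hat[S0, , drop = FALSE])
    out[r, "ise1"] <- ise_nonnull(sim$beta_true[A, , drop = FALSE],
                                  beta_hat[A, , drop = FALSE])
    out[r, "pmse"] <- pmse(fit, .subset_geno(geno, test),
                           .subset_pheno(sim$pheno, test))
  }
  structure(list(scenario = config, n_reps = n_reps,
                 metrics = as.data.frame(out),
                 metric_means = colMeans(out),
                 metric_sds = apply(out, 2L, stats::sd),
                 lambda = lam, fixed_lambda = fixed_lambda,
                 train_frac = train_frac, seeds = seeds,
                 elapsed_sec = proc.time()[["elapsed"]] - t0),
            class = "lfdat_experiment")
}

#' Tidy rejection-rate table of an experiment
#'
#' @param x an \code{"lfdat_experiment"} from \code{\link{run_type1}} or
#'   \code{\link{run_power}}.
#' @return data.frame with columns \code{method}, \code{alpha}, \code{t},
#'   \code{rate}.
#' @export
experiment_rates_df <- function(x) {
  stopifnot(inherits(x, "lfdat_experiment"))
  if (is.null(x$rejection_rate_by_time))
    stop("not a rejection-rate experiment")
  tg <- x$scenario$time_grid
  rows <- function(rates, method) do.call(rbind, lapply(
    names(rates), function(a)
      data.frame(method = method, alpha = as.numeric(a), t = tg,
                 rate = rates[[a]])))
  out <- rows(x$rejection_rate_by_time, "lfdat")
  if (!is.null(x$flm_rejection_rate_by_time))
    out <- rbind(out, rows(x$flm_rejection_rate_by_time, "smoothed_flm"))
  rownames(out) <- NULL
  out
}

#' @export
print.lfdat_experiment <- function(x, ...) {
  cat("Simulation experiment (", x$n_reps, " replicates, ",
      round(x$elapsed_sec, 1), " s)\n", sep = "")
  if (!is.null(x$rejection_rate_by_time)) {
    for (a in names(x$rejection_rate_by_time)) {
      cat("  alpha =", a, ": ",
          paste(format(x$rejection_rate_by_time[[a]], digits = 3),
                collapse = " "), "\n")
    }
  }
  if (!is.null(x$metric_means)) {
    cat("  metric means:",
        paste(names(x$metric_means),
              format(x$metric_means, digits = 4), collapse = "  "), "\n")
  }
  invisible(x)
}
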