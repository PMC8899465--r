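# Synthetic genotype and phenotype generators for the simulation studies:
# linkage-equilibrium and linkage-disequilibrium gene regions with
# MAF-class structure, and longitudinal phenotypes with MAF-dependent,
# time-varying (gene-switching) genetic effects.

.maf_bounds <- list(common = c(0.05, 0.5),
                    low    = c(0.01, 0.05),
                    rare   = c(0.0005, 0.01))

# per-SNP MAF class labels for a region class
.draw_classes <- function(region_class, L) {
  switch(region_class,
         common = rep("common", L),
         rare = rep("rare", L),
         low = rep("low", L),
         mixture1 = sample(c("common", "rare"), L, replace = TRUE,
                           prob = c(0.2, 0.8)),
         mixture2 = sample(c("common", "rare"), L, replace = TRUE,
                           prob = c(0.8, 0.2)),
         stop("unknown region class: ", region_class))
}

.draw_maf <- function(classes) {
  bounds <- .maf_bounds[classes]
  vapply(bounds, function(b) stats::runif(1L, b[1L], b[2L]), 0)
}

#' Simulation scenario configuration
#'
#' Bundles every knob of one simulation scenario.  Defaults are the study
#' conditions of the simulation design: a 1 kb region, measurement times
#' 1..9, unit error variance with compound-symmetry time correlation 0.5,
#' and a SNP density of 15 per kb.
#'
#' @param n number of subjects.
#' @param L number of SNPs in the region.
#' @param region_class one of \code{"common"}, \code{"rare"},
#'   \code{"low"}, \code{"mixture1"} (20\% common / 80\% rare),
#'   \code{"mixture2"} (80\% common / 20\% rare).
#' @param causal_prop proportion of causal SNPs; the causal count is
#'   \code{max(1, round(causal_prop * L))}.
#' @param neg_prop proportion of causal SNPs given a negative effect sign.
#' @param c effect-size constant in \eqn{\eta(s) = \ln(c) |log10 MAF_s|/2}.
#' @param theta time-effect function: \code{"case1"}
#'   (\eqn{2 + 2\sin(\pi t/12)}) or \code{"case2"}
#'   (\eqn{2 + 2\sin(\pi t/2)}, zero at t = 3 and t = 7).
#' @param rho pairwise time correlation of the errors.
#' @param sigma2 error variance.
#' @param ld \code{NULL} for linkage equilibrium, else \code{c(lo, hi)}
#'   bounds of the uniform distribution of the adjacent-pair r-squared.
#' @param time_grid raw measurement times.
#' @param region_length physical extent of the region in bp.
#' @param corr error correlation structure, \code{"cs"} (compound
#'   symmetry) or \code{"ar1"}.
#' @param seed optional integer seed fixed at the start of each generator
#'   call.
#' @return an object of class \code{"lfdat_scenario"}.
#' @export
scenario_config <- function(n = 1000L, L = 15L,
                            region_class = c("common", "rare", "low",
                                             "mixture1", "mixture2"),
                            causal_prop = 0.01, neg_prop = 0, c = 3,
                            theta = c("case1", "case2"), rho = 0.5,
                            sigma2 = 1, ld = NULL, time_grid = 1:9,
                            region_length = 1000, corr = c("cs", "ar1"),
                            seed = NULL) {
  region_class <- match.arg(region_class)
  theta <- match.arg(theta)
  corr <- match.arg(corr)
  stopifnot(n >= 2L, L >= 1L, causal_prop > 0, causal_prop <= 1,
            neg_prop >= 0, neg_prop <= 1, c > 1, sigma2 > 0,
            length(time_grid) >= 2L)
  if (!is.null(ld)) {
    if (length(ld) != 2L || ld[1L] < 0 || ld[2L] >= 1 || ld[1L] >= ld[2L])
      stop("ld must be c(lo, hi) with 0 <= lo < hi < 1")
  }
  nq <- length(time_grid)
  if (corr == "cs" && rho <= -1 / (nq - 1))
    stop("compound symmetry requires rho > -1/Q for a valid correlation")
  structure(list(n = as.integer(n), L = as.integer(L),
                 region_class = region_class, causal_prop = causal_prop,
                 neg_prop = neg_prop, c = c, theta = theta, rho = rho,
                 sigma2 = sigma2, ld = ld,
                 time_grid = as.numeric(time_grid),
                 region_length = region_length, corr = corr, seed = seed),
            class = "lfdat_scenario")
}

#' Time-effect functions
#'
#' \code{"case1"} is \eqn{\theta(t) = 2 + 2\sin(\pi t/12)} (slowly rising
#' effect); \code{"case2"} is \eqn{\theta(t) = 2 + 2\sin(\pi t/2)}, which
#' vanishes at t = 3 and t = 7 on the 1..9 grid -- the gene-switching
#' scenario.  Both act on the raw time labels.
#'
#' @param case \code{"case1"} or \code{"case2"}.
#' @return a function of time.
#' @export
theta_function <- function(case = c("case1", "case2")) {
  case <- match.arg(case)
  if (case == "case1") function(t) 2 + 2 * sin(pi * t / 12)
  else function(t) 2 + 2 * sin(pi * t / 2)
}

.region_positions <- function(L, region_length)
  (seq_len(L) - 0.5) * region_length / L

#' Simulate a linkage-equilibrium gene region
#'
#' Per SNP, draws the MAF from the uniform distribution of its class
#' (mixture classes draw class membership per SNP first), then genotypes
#' independently as Binomial(2, MAF).  SNP positions are equally spaced
#' over the region.
#'
#' @param config an \code{"lfdat_scenario"}; \code{config$ld} must be
#'   \code{NULL}.
#' @return an \code{"lfdat_genotypes"} object carrying the drawn MAFs.
#' @export
simulate_genotypes_le <- function(config) {
  stopifnot(inherits(config, "lfdat_scenario"))
  if (!is.null(config$ld))
    stop("config requests linkage disequilibrium; use simulate_genotypes_ld")
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$L; n <- config$n
  maf <- .draw_maf(.draw_classes(config$region_class, L))
  G <- matrix(stats::rbinom(n * L, 2L, rep(maf, each = n)), n, L)
  genotype_region(G, .region_positions(L, config$region_length),
                  region_length = config$region_length, maf = maf)
}

# first-order Bernoulli haplotype chain: allele at SNP l given allele a at
# SNP l-1 has P(1 | a) = p2 + r sqrt(p2 q2 / (p1 q1)) (a - p1), giving
# adjacent-allele correlation exactly r.  Feasibility requires both
# conditional probabilities to stay in [0, 1].
.chain_feasible <- function(p1, p2, r) {
  q1 <- 1 - p1; q2 <- 1 - p2
  s <- r * sqrt(p2 * q2 / (p1 * q1))
  p2 + s * (1 - p1) <= 1 && p2 + s * (0 - p1) >= 0
}

#' Simulate a gene region with adjacent-pair linkage disequilibrium
#'
#' Haplotype construction: each subject carries two independent
#' haplotypes; the allele at the first SNP is Bernoulli(MAF_1) and each
#' subsequent allele is drawn from a first-order Markov chain whose
#' conditional probabilities give an adjacent-pair allelic correlation of
#' exactly \code{+sqrt(r2)}, with \code{r2} drawn per pair from
#' \code{U(lo, hi)}.  Genotypes are the haplotype sums, so adjacent
#' genotype dosages inherit the same correlation.  (MAF, r2) draws that
#' admit no valid chain are resampled; the count is recorded in the
#' \code{"ld_resamples"} attribute.
#'
#' @param config an \code{"lfdat_scenario"} with non-\code{NULL}
#'   \code{config$ld}.
#' @return an \code{"lfdat_genotypes"} object carrying the drawn MAFs.
#' @export
simulate_genotypes_ld <- function(config) {
  stopifnot(inherits(config, "lfdat_scenario"))
  if (is.null(config$ld))
    stop("config requests linkage equilibrium; use simulate_genotypes_le")
  if (!is.null(config$seed)) set.seed(config$seed)
  L <- config$L; n <- config$n
  lo <- config$ld[1L]; hi <- config$ld[2L]
  classes <- .draw_classes(config$region_class, L)
  maf <- .draw_maf(classes)
  r <- sqrt(stats::runif(max(L - 1L, 0L), lo, hi))
  resamples <- 0L
  if (L > 1L) for (l in 2L:L) {
    tries <- 0L
    while (!.chain_feasible(maf[l - 1L], maf[l], r[l - 1L])) {
      maf[l] <- .draw_maf(classes[l])
      resamples <- resamples + 1L
      tries <- tries + 1L
      if (tries %% 50L == 0L)  # stuck pair: redraw the target r2 too
        r[l - 1L] <- sqrt(stats::runif(1L, lo, hi))
      if (tries > 1000L)
        stop("no feasible (MAF, r2) combination for SNP ", l)
    }
  }
  H <- matrix(0L, 2L * n, L)
  H[, 1L] <- stats::rbinom(2L * n, 1L, maf[1L])
  if (L > 1L) for (l in 2L:L) {
    p1 <- maf[l - 1L]; p2 <- maf[l]
    s <- r[l - 1L] * sqrt(p2 * (1 - p2) / (p1 * (1 - p1)))
    H[, l] <- stats::rbinom(2L * n, 1L, p2 + s * (H[, l - 1L] - p1))
  }
  G <- H[seq_len(n), , drop = FALSE] +
    H[n + seq_len(n), , drop = FALSE]
  out <- genotype_region(G, .region_positions(L, config$region_length),
                         region_length = config$region_length, maf = maf)
  attr(out, "ld_resamples") <- resamples
  attr(out, "ld_r2_target") <- r^2
  out
}

#' Simulate phenotypes under the null (no genetic effect)
#'
#' \eqn{y_i(t) = \mu(t) + \varepsilon_i(t)} with \eqn{\mu(t) = 1} and
#' errors multivariate normal with variance \code{sigma2} and pairwise
#' time correlation \code{rho} (compound symmetry by default, AR(1)
#' optionally), independent across subjects.
#'
#' @param config an \code{"lfdat_scenario"}.
#' @param n number of subjects (defaults to \code{config$n}).
#' @return an \code{"lfdat_phenotypes"} object.
#' @export
simulate_null_phenotypes <- function(config, n = config$n) {
  stopifnot(inherits(config, "lfdat_scenario"))
  nq <- length(config$time_grid)
  R <- if (config$corr == "cs") {
    M <- matrix(config$rho, nq, nq); diag(M) <- 1; M
  } else {
    config$rho^abs(outer(seq_len(nq), seq_len(nq), `-`))
  }
  ch <- tryCatch(chol(config$sigma2 * R), error = function(e)
    stop("error correlation matrix is not positive definite"))
  E <- matrix(stats::rnorm(n * nq), n, nq) %*% ch
  longitudinal_phenotype(1 + E, config$time_grid)
}

#' Draw the causal-variant effect specification
#'
#' Selects the causal set A uniformly among polymorphic SNPs
#' (\code{|A| = max(1, round(causal_prop * L))}), computes the genetic
#' effect sizes \eqn{\eta(s) = \ln(c) |log10 MAF_s| / 2} from the drawn
#' MAF parameters, and assigns \code{round(neg_prop * |A|)} negative
#' signs at random.
#'
#' @param config an \code{"lfdat_scenario"}.
#' @param geno the simulated \code{"lfdat_genotypes"}.
#' @return an object of class \code{"lfdat_effect"} with
#'   \code{causal_indices}, \code{signs}, \code{eta} and \code{theta_fn}.
#' @export
make_effect <- function(config, geno) {
  stopifnot(inherits(config, "lfdat_scenario"),
            inherits(geno, "lfdat_genotypes"))
  candidates <- which(geno$maf > 0)
  if (length(candidates) == 0L) stop("no polymorphic SNPs to pick from")
  size <- max(1L, round(config$causal_prop * config$L))
  size <- min(size, length(candidates))
  A <- sort(sample(candidates, size))
  signs <- rep(1, size)
  n_neg <- round(config$neg_prop * size)
  if (n_neg > 0L) signs[sample(size, n_neg)] <- -1
  structure(list(causal_indices = A, signs = signs,
                 eta = log(config$c) * abs(log10(geno$maf[A])) / 2,
                 theta_fn = config$theta),
            class = "lfdat_effect")
}

#' Simulate phenotypes under the alternative
#'
#' Adds \eqn{\sum_{s \in A} x_{is} \beta_s(t)} to the null phenotypes,
#' with \eqn{\beta_s(t) = \pm \eta(s) \theta(t)} evaluated at the raw
#' time labels.  Also returns the true effect grid (SNPs x time points,
#' zero off the causal set) that drives the ISE metrics.
#'
#' @param config an \code{"lfdat_scenario"}.
#' @param geno the simulated \code{"lfdat_genotypes"}.
#' @param effect an \code{"lfdat_effect"} from \code{\link{make_effect}}.
#' @return list with \code{pheno} (an \code{"lfdat_phenotypes"}) and
#'   \code{beta_true} (L x (Q+1) matrix).
#' @export
simulate_alt_phenotypes <- function(config, geno, effect) {
  stopifnot(inherits(effect, "lfdat_effect"))
  theta <- theta_function(effect$theta_fn)(config$time_grid)
  beta_true <- matrix(0, config$L, length(config$time_grid))
  A <- effect$causal_indices
  beta_true[A, ] <- outer(effect$signs * effect$eta, theta)
  null_ph <- simulate_null_phenotypes(config, nrow(geno$G))
  Y <- null_ph$Y + geno$G[, A, drop = FALSE] %*% beta_true[A, , drop = FALSE]
  list(pheno = longitudinal_phenotype(Y, config$time_grid),
       beta_true = beta_true)
}

#' @export
print.lfdat_scenario <- function(x, ...) {
  cat("Simulation scenario:", x$region_class, "region, n =", x$n,
      ", L =", x$L, if (is.null(x$ld)) "(LE)" else
        paste0("(LD r2 ~ U(", x$ld[1L], ", ", x$ld[2L], "))"), "\n")
  cat("  effect: c =", x$c, ", causal", x$causal_prop * 100,
      "%, negative", x$neg_prop * 100, "%, theta =", x$theta, "\n")
  invisible(x)
}
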