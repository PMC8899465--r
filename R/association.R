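# Hypothesis test of no genetic effect, H0: beta(s, t) = 0, via the
# F statistic comparing the null residual sum of squares (centered
# phenotypes) with the residual sum of squares of the fitted
# function-on-function regression.  The tabulated quantity is the per-time
# F; an aggregate over the whole grid is provided as a clearly labelled
# extra.

#' Per-time-point F test
#'
#' At time point \code{t_q} the statistic is
#' \deqn{F = \frac{(RSS_0(t_q) - RSS_1(t_q))/K}{RSS_1(t_q)/(n - K - 1)}}
#' with \code{RSS0} the squared centered phenotypes, \code{RSS1} the fit
#' residuals, and \code{K} the number of estimated surface coefficients;
#' the p-value is the upper tail of \code{F(K, n - K - 1)}.
#'
#' @param fit an \code{"lfdat_fofr"} fit.
#' @param time_index index q of the time point (1-based).
#' @return named vector with elements \code{F} and \code{p}.
#' @export
f_test_pointwise <- function(fit, time_index) {
  stopifnot(inherits(fit, "lfdat_fofr"))
  K <- fit$K; n <- fit$n
  if (n - K - 1 <= 0)
    stop("degrees of freedom exhausted: need n > K + 1 (n = ", n,
         ", K = ", K, ")")
  q <- as.integer(time_index)
  if (q < 1L || q > length(fit$time_grid)) stop("time_index out of range")
  rss0 <- fit$rss0_by_time[q]; rss1 <- fit$rss1_by_time[q]
  Fv <- max(0, (rss0 - rss1) / K) / (rss1 / (n - K - 1))
  c(F = Fv, p = stats::pf(Fv, K, n - K - 1, lower.tail = FALSE))
}

#' F tests at every time point, plus a whole-grid aggregate
#'
#' Runs \code{\link{f_test_pointwise}} at every measurement time and also
#' reports a global statistic built from the residual sums of squares
#' summed over the whole time grid with the same \code{(K, n - K - 1)}
#' reference distribution.  The per-time values are the primary output;
#' the global value is a convenience summary of the whole-surface null.
#'
#' @param fit an \code{"lfdat_fofr"} fit.
#' @param alphas significance levels at which rejection indicators are
#'   reported.
#' @return an object of class \code{"lfdat_test"} with \code{f_by_time},
#'   \code{p_by_time}, \code{df1}, \code{df2}, \code{f_global},
#'   \code{p_global} and \code{alpha_decisions} (one logical vector per
#'   level).
#' @export
f_test_all <- function(fit, alphas = c(0.05, 0.01, 0.001)) {
  stopifnot(inherits(fit, "lfdat_fofr"))
  K <- fit$K; n <- fit$n
  if (n - K - 1 <= 0)
    stop("degrees of freedom exhausted: need n > K + 1 (n = ", n,
         ", K = ", K, ")")
  nq <- length(fit$time_grid)
  res <- vapply(seq_len(nq), function(q) f_test_pointwise(fit, q),
                c(F = 0, p = 0))
  rss0 <- sum(fit$rss0_by_time); rss1 <- sum(fit$rss1_by_time)
  f_global <- max(0, (rss0 - rss1) / K) / (rss1 / (n - K - 1))
  p_global <- stats::pf(f_global, K, n - K - 1, lower.tail = FALSE)
  decisions <- lapply(alphas, function(a) unname(res["p", ] < a))
  names(decisions) <- as.character(alphas)
  structure(list(f_by_time = unname(res["F", ]),
                 p_by_time = unname(res["p", ]),
                 df1 = K, df2 = n - K - 1,
                 f_global = f_global, p_global = p_global,
                 time_grid = fit$time_grid,
                 alpha_decisions = decisions),
            class = "lfdat_test")
}

#' @export
print.lfdat_test <- function(x, ...) {
  cat("Gene-region association test (", x$df1, ",", x$df2,
      ") df\n", sep = "")
  tab <- rbind(F = signif(x$f_by_time, 4), p = signif(x$p_by_time, 4))
  colnames(tab) <- paste0("t=", format(x$time_grid))
  print(tab)
  cat("whole-grid aggregate: F =", signif(x$f_global, 4),
      " p =", signif(x$p_global, 4), "\n")
  invisible(x)
}
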