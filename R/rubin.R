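# Rubin's rules: combining estimates and standard errors across the M
# completed datasets.
#
# Q-bar = (1/M) sum Q_m                      (pooled point estimate)
# W-bar = (1/M) sum W_m^2                    (within-imputation variance)
# B     = (1/(M-1)) sum (Q_m - Q-bar)^2      (between-imputation variance)
# T^2   = W-bar + (1 + 1/M) B                (total variance)
#
# Intervals use normal quantiles; the small-sample degrees-of-freedom
# correction is deliberately omitted (see the methods vignette).

#' Pool estimates across imputations with Rubin's rules
#'
#' @param estimates numeric vector of per-imputation point estimates Q_m.
#' @param std_errors numeric vector of per-imputation standard errors W_m
#'   (same length, all >= 0).
#' @param level two-sided confidence level (default 0.95).
#' @return an object of class \code{pooled_estimate} with the pooled
#'   estimate, within/between variances, total standard error T, and a
#'   normal-quantile confidence interval.
#' @examples
#' pool(c(0.8, 0.9, 1.0), c(0.1, 0.1, 0.1))
#' @export
pool <- function(estimates, std_errors, level = 0.95) {
  M <- length(estimates)
  if (M < 2) stop("M must be >= 2: between-imputation variance is undefined")
  if (length(std_errors) != M) stop("estimates and std_errors must have equal length")
  if (any(std_errors < 0)) stop("standard errors must be >= 0")
  qbar <- mean(estimates)
  wbar <- mean(std_errors^2)
  b <- sum((estimates - qbar)^2) / (M - 1)
  tvar <- wbar + (1 + 1 / M) * b
  tse <- sqrt(tvar)
  z <- z_quantile(level)
  structure(
    list(estimates = estimates, std_errors = std_errors, M = M,
         qbar = qbar, within = wbar, between = b, t_se = tse,
         level = level, ci = c(qbar - z * tse, qbar + z * tse)),
    class = "pooled_estimate"
  )
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("Pooled estimate over M=%d imputations\n", x$M))
  cat(sprintf("  Q-bar = %.6g  (W-bar = %.4g, B = %.4g, T = %.4g)\n",
              x$qbar, x$within, x$between, x$t_se))
  cat(sprintf("  %g%% CI: %.6g to %.6g\n", 100 * x$level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Pool a log-scale coefficient and report as a ratio
#'
#' Pooling is performed on the model's natural (log-link) coefficient
#' scale, never on exponentiated ratios; the pooled coefficient and its
#' interval are exponentiated only for reporting.  A two-sided p-value from
#' the normal reference tests the null ratio of 1.
#'
#' @param coefs per-imputation coefficients on the log scale.
#' @param std_errors per-imputation standard errors on the log scale.
#' @param level two-sided confidence level.
#' @return an object of class \code{pooled_ratio}: the underlying
#'   \code{pooled_estimate} plus \code{ratio}, \code{ratio_ci},
#'   \code{p_value}.
#' @export
pool_log_scale <- function(coefs, std_errors, level = 0.95) {
  pe <- pool(coefs, std_errors, level)
  p_value <- if (pe$t_se > 0) 2 * stats::pnorm(-abs(pe$qbar) / pe$t_se)
             else if (pe$qbar == 0) NA_real_ else 0
  out <- c(pe, list(ratio = exp(pe$qbar), ratio_ci = exp(pe$ci), p_value = p_value))
  class(out) <- c("pooled_ratio", "pooled_estimate")
  out
}

#' @export
print.pooled_ratio <- function(x, ...) {
  cat(sprintf("Pooled ratio over M=%d imputations\n", x$M))
  cat(sprintf("  ratio = %.2f, %g%% CI %.2f-%.2f, P = %.3g\n",
              x$ratio, 100 * x$level, x$ratio_ci[1], x$ratio_ci[2], x$p_value))
  cat(sprintf("  (log scale: Q-bar = %.4g, W-bar = %.4g, B = %.4g, T = %.4g)\n",
              x$qbar, x$within, x$between, x$t_se))
  invisible(x)
}

#' Write a pooling report
#'
#' Plain-text and machine-readable (key = value) report of per-imputation
#' estimates and the pooled result.
#'
#' @param x a \code{pooled_estimate} or \code{pooled_ratio}.
#' @param path output file; a second file with suffix \code{.kv} holds the
#'   machine-readable form.
#' @return invisibly, the paths written.
#' @export
write_pooled <- function(x, path) {
  txt <- utils::capture.output(print(x))
  writeLines(txt, path)
  kv <- c(
    sprintf("M = %d", x$M),
    sprintf("estimate_%d = %.15g", seq_len(x$M), x$estimates),
    sprintf("std_error_%d = %.15g", seq_len(x$M), x$std_errors),
    sprintf("qbar = %.15g", x$qbar),
    sprintf("within = %.15g", x$within),
    sprintf("between = %.15g", x$between),
    sprintf("t_se = %.15g", x$t_se),
    sprintf("ci_lo = %.15g", x$ci[1]),
    sprintf("ci_hi = %.15g", x$ci[2])
  )
  if (inherits(x, "pooled_ratio")) {
    kv <- c(kv,
            sprintf("ratio = %.15g", x$ratio),
            sprintf("ratio_ci_lo = %.15g", x$ratio_ci[1]),
            sprintf("ratio_ci_hi = %.15g", x$ratio_ci[2]),
            sprintf("p_value = %.15g", x$p_value))
  }
  kvpath <- paste0(path, ".kv")
  writeLines(kv, kvpath)
  invisible(c(path, kvpath))
}
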