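# Inverse-variance random-effects pooling (DerSimonian-Laird) and
# heterogeneity statistics on the log-ratio scale.

check_ys <- function(y, s, min_k = 1L) {
  stopifnot(length(y) == length(s))
  if (any(!is.finite(y)) || any(!is.finite(s)))
    stop("log effects and standard errors must be finite", call. = FALSE)
  if (any(s <= 0))
    stop("standard errors must be positive", call. = FALSE)
  if (length(y) < min_k)
    stop("at least ", min_k, " studies required, got ", length(y),
         call. = FALSE)
  invisible(length(y))
}

#' Cochran's Q heterogeneity statistic
#'
#' With fixed-effect weights \eqn{w_i = 1/s_i^2} and the fixed-effect pooled
#' mean \eqn{\hat y_F = \sum w_i y_i / \sum w_i}, returns
#' \eqn{Q = \sum w_i (y_i - \hat y_F)^2}.
#'
#' @param y Log-scale effect estimates (one per study).
#' @param s Their standard errors, positive.
#' @return Q, a nonnegative scalar.
#' @export
cochran_q <- function(y, s) {
  check_ys(y, s, min_k = 2L)
  w <- 1 / s^2
  yf <- sum(w * y) / sum(w)
  sum(w * (y - yf)^2)
}

#' DerSimonian-Laird between-study variance
#'
#' Moment estimator
#' \eqn{\hat\tau^2 = \max(0, (Q - (k-1)) / (\sum w - \sum w^2 / \sum w))},
#' zero-truncated.
#'
#' @param q Cochran's Q statistic.
#' @param w Fixed-effect weights \eqn{1/s_i^2}, positive, length `k >= 2`.
#' @return \eqn{\hat\tau^2 \ge 0} on the squared log scale.
#' @export
tau_squared_dl <- function(q, w) {
  stopifnot(length(w) >= 2L, all(is.finite(w)), all(w > 0),
            is.finite(q), q >= 0)
  k <- length(w)
  max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
}

#' I-squared heterogeneity percentage
#'
#' \eqn{I^2 = 100 \max(0, (Q - (k-1))/Q)}; defined as 0 when Q = 0.
#'
#' @param q Cochran's Q statistic (nonnegative).
#' @param k Number of studies, `>= 2`.
#' @return Percentage in \[0, 100\].
#' @export
i_squared <- function(q, k) {
  stopifnot(is.finite(q), q >= 0, k >= 2L)
  if (q == 0) return(0)
  100 * max(0, (q - (k - 1)) / q)
}

#' Two-sided Wald p-value for a log effect
#'
#' \eqn{p = 2(1 - \Phi(|y|/s))}, the normal-approximation p-value implied by
#' a published ratio estimate and confidence interval.
#'
#' @param y Log effect(s).
#' @param s Standard error(s), positive. Vectorized.
#' @return Two-sided p-value(s) in \[0, 1\].
#' @export
wald_p <- function(y, s) {
  stopifnot(length(y) == length(s))
  if (any(!is.finite(s)) || any(s <= 0))
    stop("standard errors must be positive and finite", call. = FALSE)
  2 * stats::pnorm(-abs(y) / s)
}

#' Random-effects pooling of one meta-analysis
#'
#' DerSimonian-Laird inverse-variance synthesis: random-effects weights
#' \eqn{w_i^* = 1/(s_i^2 + \hat\tau^2)}, pooled log effect
#' \eqn{\hat y = \sum w_i^* y_i / \sum w_i^*}, standard error
#' \eqn{(\sum w_i^*)^{-1/2}}, normal (z) confidence interval and two-sided
#' Wald p-value. Heterogeneity (Q, \eqn{\tau^2}, \eqn{I^2}) is attached.
#'
#' @param y Log-scale effect estimates, `k >= 2`.
#' @param s Their standard errors, positive.
#' @param level Confidence level for the pooled interval, default `0.95`.
#' @return An object of class `pooled_result`: a list with `k`, `y_pooled`,
#'   `se_pooled`, `ci_lower`, `ci_upper` (log scale), `p_value`, `q_stat`,
#'   `tau2`, `i2`.
#' @examples
#' pool_random_effects(c(0.2, 0.4, 0.6), c(0.1, 0.1, 0.1))
#' @export
pool_random_effects <- function(y, s, level = 0.95) {
  k <- check_ys(y, s, min_k = 2L)
  w <- 1 / s^2
  q <- cochran_q(y, s)
  tau2 <- tau_squared_dl(q, w)
  wstar <- 1 / (s^2 + tau2)
  yp <- sum(wstar * y) / sum(wstar)
  sep <- 1 / sqrt(sum(wstar))
  z <- stats::qnorm((1 + level) / 2)
  structure(
    list(k = k, y_pooled = yp, se_pooled = sep,
         ci_lower = yp - z * sep, ci_upper = yp + z * sep,
         p_value = wald_p(yp, sep),
         q_stat = q, tau2 = tau2, i2 = i_squared(q, k)),
    class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat(sprintf("Random-effects pooling (DerSimonian-Laird), k = %d\n", x$k))
  cat(sprintf("  pooled ratio %.4f [%.4f, %.4f], p = %.4g\n",
              exp(x$y_pooled), exp(x$ci_lower), exp(x$ci_upper), x$p_value))
  cat(sprintf("  Q = %.3f, tau^2 = %.4f, I^2 = %.1f%%\n",
              x$q_stat, x$tau2, x$i2))
  invisible(x)
}
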