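# The two reporting-bias statistics: Egger regression asymmetry
# (small-study effect) and the excess-significance test.

#' Egger regression asymmetry test for small-study effects
#'
#' Small studies that only reach print when their estimates are large leave
#' a signature asymmetry in the funnel plot. The classic regression form of
#' the test fits, by ordinary least squares, the standardized effect
#' \eqn{t_i = y_i / s_i} on precision \eqn{x_i = 1/s_i}; the intercept
#' estimates the asymmetry, and its t statistic (with `k - 2` degrees of
#' freedom) gives the two-sided p-value. A meta-analysis is flagged at
#' `p < alpha` (default 0.10, the conventional threshold for this
#' low-powered test).
#'
#' Fewer than three studies cannot support the regression; such
#' meta-analyses are returned as ineligible rather than an error, so
#' corpus-level tabulations can count them. Identical standard errors make
#' the regressor constant and raise an error.
#'
#' @param y Log-scale effect estimates.
#' @param s Their standard errors, positive.
#' @param alpha Flagging threshold on the two-sided p, default `0.10`.
#' @return An object of class `egger_result`: `k`, `eligible`, `intercept`,
#'   `intercept_se`, `t_stat`, `df`, `p_two_sided`, `flagged`.
#' @examples
#' egger_test(c(0.1, -0.1, 0.2, -0.2, 0), c(0.1, 0.1, 0.2, 0.2, 0.15))
#' @export
egger_test <- function(y, s, alpha = 0.10) {
  k <- check_ys(y, s, min_k = 1L)
  if (k < 3L) {
    return(structure(
      list(k = k, eligible = FALSE, intercept = NA_real_,
           intercept_se = NA_real_, t_stat = NA_real_, df = NA_integer_,
           p_two_sided = NA_real_, flagged = FALSE),
      class = "egger_result"))
  }
  x <- 1 / s
  if (diff(range(x)) < .Machine$double.eps * max(x))
    stop("all standard errors identical: Egger regressor is constant",
         call. = FALSE)
  fit <- stats::lm(I(y / s) ~ x)
  sm <- summary(fit)$coefficients
  b0 <- sm["(Intercept)", "Estimate"]
  se0 <- sm["(Intercept)", "Std. Error"]
  tval <- b0 / se0
  p <- 2 * stats::pt(-abs(tval), df = k - 2L)
  structure(
    list(k = k, eligible = TRUE, intercept = b0, intercept_se = se0,
         t_stat = tval, df = k - 2L, p_two_sided = p,
         flagged = p < alpha),
    class = "egger_result")
}

#' @export
print.egger_result <- function(x, ...) {
  if (!x$eligible) {
    cat(sprintf("Egger test: ineligible (k = %d < 3)\n", x$k))
    return(invisible(x))
  }
  cat(sprintf(
    "Egger test, k = %d: intercept %.4f (SE %.4f), t = %.3f on %d df, p = %.4g%s\n",
    x$k, x$intercept, x$intercept_se, x$t_stat, x$df, x$p_two_sided,
    if (x$flagged) " [small-study effect]" else ""))
  invisible(x)
}

#' Plausible effect for power calculations
#'
#' The excess-significance test needs a plausible true effect for each
#' meta-analysis; it is taken to be the effect of the most precise primary
#' study (smallest standard error). Ties on precision are broken toward the
#' effect closest to the null (smallest `|y|`), then by input order.
#'
#' @param y Log-scale effect estimates, `k >= 1`.
#' @param s Their standard errors, positive.
#' @return The selected study's log effect, \eqn{\theta^*}.
#' @export
plausible_effect <- function(y, s) {
  check_ys(y, s, min_k = 1L)
  idx <- order(s, abs(y), seq_along(y))[1]
  y[idx]
}

#' Power of a primary study against a plausible effect
#'
#' Power of the two-sided level-`alpha` Wald test when the true log effect
#' is \eqn{\theta^*} and the study's standard error is `s`:
#' \deqn{1 - \Phi(z_{1-\alpha/2} - |\theta^*|/s) +
#'       \Phi(-z_{1-\alpha/2} - |\theta^*|/s).}
#' Equals `alpha` when \eqn{\theta^* = 0} and increases monotonically in
#' \eqn{|\theta^*|/s}.
#'
#' @param s Standard error(s), positive. Vectorized.
#' @param theta_star Plausible log effect.
#' @param alpha Per-study significance level, default `0.05`.
#' @return Power value(s) in \[`alpha`, 1).
#' @export
study_power <- function(s, theta_star, alpha = 0.05) {
  if (any(!is.finite(s)) || any(s <= 0))
    stop("standard errors must be positive and finite", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1, is.finite(theta_star))
  zc <- stats::qnorm(1 - alpha / 2)
  shift <- abs(theta_star) / s
  stats::pnorm(shift - zc) + stats::pnorm(-zc - shift)
}

#' Count of nominally significant primary studies
#'
#' The observed count O: studies whose two-sided Wald p-value (recomputed
#' from `y/s` under normality) is strictly below `alpha`. With
#' `direction = "theta"`, only studies significant in the direction of a
#' supplied plausible effect are counted.
#'
#' @param y Log-scale effect estimates.
#' @param s Their standard errors, positive.
#' @param alpha Per-study significance level, default `0.05`.
#' @param direction `"either"` (default) counts significance in either
#'   direction; `"theta"` restricts to the sign of `theta_star`.
#' @param theta_star Required when `direction = "theta"`.
#' @return Integer O in \[0, k\].
#' @export
observed_significant <- function(y, s, alpha = 0.05,
                                 direction = c("either", "theta"),
                                 theta_star = NULL) {
  check_ys(y, s, min_k = 1L)
  direction <- match.arg(direction)
  sig <- wald_p(y, s) < alpha
  if (direction == "theta") {
    if (is.null(theta_star))
      stop("theta_star required for direction = \"theta\"", call. = FALSE)
    sig <- sig & (sign(y) == sign(theta_star) | theta_star == 0)
  }
  sum(sig)
}

#' Excess-significance test
#'
#' Asks whether a meta-analysis contains more nominally significant primary
#' studies than its power can explain. The expected count E is the sum over
#' studies of [study_power()] at the plausible effect \eqn{\theta^*} (the
#' most precise study's effect, [plausible_effect()]); the observed count O
#' comes from [observed_significant()]. O and E are compared with the
#' binomial-type chi-square
#' \deqn{\chi^2 = (O-E)^2/E + (O-E)^2/(k-E)} on 1 degree of freedom.
#' The test flags excess significance only when `O > E` and the one-sided
#' p-value is below `alpha_test / 2` — equivalently a two-sided `p < 0.10`
#' with `O > E` at the defaults.
#'
#' Meta-analyses with fewer than 3 studies are returned as ineligible. A
#' degenerate expected count (E = 0 or E = k, possible only at the float
#' boundary) is clamped to `[k * 1e-9, k * (1 - 1e-9)]` before the
#' chi-square, and the clamping is recorded in the result.
#'
#' @param y Log-scale effect estimates.
#' @param s Their standard errors, positive.
#' @param alpha_study Per-study significance level used for O and the power
#'   calculations, default `0.05`.
#' @param alpha_test Two-sided flagging threshold, default `0.10`
#'   (one-sided 0.05 for O > E).
#' @param direction Passed to [observed_significant()].
#' @return An object of class `excess_result`: `k`, `eligible`, `observed`,
#'   `expected`, `theta_star`, `powers`, `chi2`, `p_value` (two-sided),
#'   `p_one_sided`, `o_gt_e`, `flagged`, `clamped`.
#' @export
excess_significance_test <- function(y, s, alpha_study = 0.05,
                                     alpha_test = 0.10,
                                     direction = c("either", "theta")) {
  k <- check_ys(y, s, min_k = 1L)
  direction <- match.arg(direction)
  if (k < 3L) {
    return(structure(
      list(k = k, eligible = FALSE, observed = NA_integer_,
           expected = NA_real_, theta_star = NA_real_, powers = NULL,
           chi2 = NA_real_, p_value = NA_real_, p_one_sided = NA_real_,
           o_gt_e = FALSE, flagged = FALSE, clamped = FALSE),
      class = "excess_result"))
  }
  theta <- plausible_effect(y, s)
  powers <- study_power(s, theta, alpha_study)
  e <- sum(powers)
  o <- observed_significant(y, s, alpha_study, direction,
                            theta_star = theta)
  clamped <- e < k * 1e-9 || e > k * (1 - 1e-9)
  e_used <- min(max(e, k * 1e-9), k * (1 - 1e-9))
  chi2 <- (o - e_used)^2 / e_used + (o - e_used)^2 / (k - e_used)
  p_two <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  o_gt_e <- o > e
  p_one <- if (o_gt_e) p_two / 2 else 1 - p_two / 2
  structure(
    list(k = k, eligible = TRUE, observed = as.integer(o), expected = e,
         theta_star = theta, powers = powers, chi2 = chi2,
         p_value = p_two, p_one_sided = p_one, o_gt_e = o_gt_e,
         flagged = o_gt_e && p_two < alpha_test, clamped = clamped),
    class = "excess_result")
}

#' @export
print.excess_result <- function(x, ...) {
  if (!x$eligible) {
    cat(sprintf("Excess-significance test: ineligible (k = %d < 3)\n", x$k))
    return(invisible(x))
  }
  cat(sprintf(
    "Excess-significance test, k = %d: O = %d, E = %.2f (theta* ratio %.3f)\n",
    x$k, x$observed, x$expected, exp(x$theta_star)))
  cat(sprintf("  chi^2 = %.3f, two-sided p = %.4g%s\n",
              x$chi2, x$p_value,
              if (x$flagged) " [excess significance]" else ""))
  invisible(x)
}
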