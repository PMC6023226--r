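# Independent oracles, coded directly from the defining formulas and kept
# free of any package internals.

# DerSimonian-Laird random-effects synthesis by direct formula evaluation.
dl_oracle <- function(y, s) {
  k <- length(y)
  w <- 1 / s^2
  yf <- sum(w * y) / sum(w)
  q <- sum(w * (y - yf)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (s^2 + tau2)
  mu <- sum(ws * y) / sum(ws)
  se <- sqrt(1 / sum(ws))
  list(mu = mu, se = se, q = q, tau2 = tau2,
       i2 = if (q == 0) 0 else 100 * max(0, (q - (k - 1)) / q),
       p = 2 * pnorm(-abs(mu) / se))
}

# Closed-form simple linear regression of t on x: intercept, its SE, and
# the two-sided p on k - 2 df.
ols_intercept_oracle <- function(t, x) {
  k <- length(t)
  sxx <- sum((x - mean(x))^2)
  b1 <- sum((x - mean(x)) * (t - mean(t))) / sxx
  b0 <- mean(t) - b1 * mean(x)
  res <- t - b0 - b1 * x
  sigma2 <- sum(res^2) / (k - 2)
  se0 <- sqrt(sigma2 * (1 / k + mean(x)^2 / sxx))
  list(intercept = b0, se = se0,
       p = 2 * pt(-abs(b0 / se0), df = k - 2))
}

# Exact Poisson-binomial upper tail P(X >= o) by full enumeration of the
# 2^k independent-study outcomes.
pb_tail_oracle <- function(probs, o) {
  k <- length(probs)
  stopifnot(k <= 16)
  probs <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  m <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  logp <- m %*% log(probs) + (1 - m) %*% log1p(-probs)
  sum(exp(logp)[rowSums(m) >= o])
}

# Small hand-built corpus: three meta-analyses in two research areas.
toy_corpus_df <- function() {
  data.frame(
    meta_id = rep(c("pa1", "pa2", "diet1"), times = c(5, 2, 4)),
    research_area = rep(c("physical_activity", "physical_activity",
                          "diet"), times = c(5, 2, 4)),
    exposure = rep(c("walking", "cycling", "sodium"), times = c(5, 2, 4)),
    outcome = "all_cause_mortality",
    study_id = c(paste0("s", 1:5), paste0("t", 1:2), paste0("u", 1:4)),
    effect = c(0.70, 0.75, 0.60, 0.85, 0.65,
               0.80, 0.90,
               1.20, 1.35, 1.10, 1.25),
    ci_lower = c(0.60, 0.55, 0.40, 0.70, 0.45,
                 0.65, 0.75,
                 1.05, 1.10, 0.95, 1.00),
    ci_upper = c(0.82, 1.02, 0.90, 1.03, 0.94,
                 0.98, 1.08,
                 1.37, 1.66, 1.27, 1.56),
    measure = "RR",
    n_participants = c(1000L, 500L, 300L, 2000L, 400L,
                       1500L, 2500L,
                       800L, 600L, 3000L, NA),
    n_deaths = c(250L, 120L, 80L, 500L, 90L,
                 400L, 600L,
                 210L, 150L, 800L, NA),
    stringsAsFactors = FALSE)
}

robis_fixture_path <- function() {
  system.file("extdata", "robis_table1.csv", package = "biasaudit",
              mustWork = TRUE)
}
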