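# Synthetic meta-analytic corpora with known truth: normal-normal effects,
# between-study heterogeneity, and a file-drawer publication-selection
# mechanism. Used to exercise the pipeline and to estimate the bias tests'
# operating characteristics.

#' Configuration for synthetic corpus generation
#'
#' The generative model per primary study: a standard error `s` drawn
#' log-uniformly from `(se_min, se_max)` (giving the long-tailed study-size
#' mix typical of funnel plots), a study-level true effect
#' \eqn{\theta_i \sim N(\theta, \tau^2)}, an estimate
#' \eqn{y \sim N(\theta_i, s^2)}, and a death count `round(deaths_c / s^2)`
#' linking study size to precision. Publication selection is the simplest
#' file-drawer mechanism: a study significant at the two-sided 0.05 level
#' is always published; a non-significant one is published with probability
#' `p_publish_nonsig` (1 = no selection). Candidates are drawn until
#' `k_published` studies are accepted.
#'
#' Defaults emulate a behavior-mortality literature: 9 primary studies per
#' meta-analysis, a modest relative risk (`exp(theta)` = 1.3), moderate
#' heterogeneity (`tau` = 0.15), and no selection.
#'
#' @param theta True log effect.
#' @param tau Between-study SD on the log scale, `>= 0`.
#' @param k_published Published studies per meta-analysis, `>= 3`.
#' @param se_min,se_max Bounds of the log-uniform SE distribution,
#'   `0 < se_min < se_max` (or `se_min == se_max` for a fixed SE).
#' @param p_publish_nonsig Publication probability for non-significant
#'   studies, in \[0, 1\].
#' @param deaths_c Constant in `deaths = round(deaths_c / s^2)`.
#' @param n_metas Number of meta-analyses per corpus, `>= 1`.
#' @param research_area Label assigned to generated meta-analyses.
#' @param seed Integer seed; all randomness derives from it.
#' @param select_alpha Two-sided level at which selection always publishes.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(theta = log(1.3), tau = 0.15,
                             k_published = 9L, se_min = 0.05,
                             se_max = 0.5, p_publish_nonsig = 1,
                             deaths_c = 1.0, n_metas = 20L,
                             research_area = "diet", seed = 1L,
                             select_alpha = 0.05) {
  stopifnot(is.finite(theta), is.finite(tau), tau >= 0,
            k_published >= 3L,
            se_min > 0, se_max >= se_min,
            p_publish_nonsig >= 0, p_publish_nonsig <= 1,
            deaths_c > 0, n_metas >= 0L,
            select_alpha > 0, select_alpha < 1)
  if (!research_area %in% research_areas())
    stop("research_area must be one of: ",
         paste(research_areas(), collapse = ", "), call. = FALSE)
  structure(list(theta = theta, tau = tau,
                 k_published = as.integer(k_published),
                 se_min = se_min, se_max = se_max,
                 p_publish_nonsig = p_publish_nonsig,
                 deaths_c = deaths_c, n_metas = as.integer(n_metas),
                 research_area = research_area, seed = as.integer(seed),
                 select_alpha = select_alpha),
            class = "synthetic_config")
}

# sub-seeds below 2^31 derived reproducibly from the master seed, so each
# meta-analysis has an independent, restartable stream
derive_subseeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Draw one primary study from the generative model
#'
#' Uses the current RNG stream. The returned study is exactly invertible:
#' [study_log_stats()] on its effect and CI recovers the simulated `(y, s)`.
#'
#' @param config A [synthetic_config()].
#' @param study_id Label for the generated study.
#' @return A one-row tibble with the corpus study columns plus `y` and `s`.
#' @export
simulate_study <- function(config, study_id = "study_1") {
  stopifnot(inherits(config, "synthetic_config"))
  s <- exp(stats::runif(1, log(config$se_min), log(config$se_max)))
  theta_i <- config$theta + stats::rnorm(1, 0, config$tau)
  y <- stats::rnorm(1, theta_i, s)
  z <- stats::qnorm(0.975)
  deaths <- as.integer(round(config$deaths_c / s^2))
  tibble::tibble(
    study_id = study_id, effect = exp(y),
    ci_lower = exp(y - z * s), ci_upper = exp(y + z * s),
    measure = "RR",
    n_participants = as.integer(pmin(.Machine$integer.max,
                                     round(20 * deaths))),
    n_deaths = deaths, y = y, s = s)
}

#' File-drawer publication decision
#'
#' A study significant at the two-sided `select_alpha` level is always
#' published; otherwise it is published with probability
#' `p_publish_nonsig`. Consumes one uniform draw only for non-significant
#' studies.
#'
#' @param p_two_sided The study's two-sided p-value.
#' @param config A [synthetic_config()].
#' @return Logical: publish?
#' @export
apply_selection <- function(p_two_sided, config) {
  stopifnot(inherits(config, "synthetic_config"),
            p_two_sided >= 0, p_two_sided <= 1)
  if (p_two_sided < config$select_alpha) return(TRUE)
  if (config$p_publish_nonsig >= 1) return(TRUE)
  if (config$p_publish_nonsig <= 0) return(FALSE)
  stats::runif(1) < config$p_publish_nonsig
}

#' Generate one meta-analysis under selection
#'
#' Draws candidate studies and applies [apply_selection()] until
#' `k_published` studies are accepted (cap: 10^6 candidates). The number of
#' suppressed candidates is recorded in the `suppressed` attribute.
#'
#' @param config A [synthetic_config()].
#' @param meta_id Label for the generated meta-analysis.
#' @return A tibble of `k_published` study rows (corpus schema) with
#'   attribute `suppressed`.
#' @export
generate_meta <- function(config, meta_id = "meta_1") {
  stopifnot(inherits(config, "synthetic_config"))
  accepted <- vector("list", config$k_published)
  n_acc <- 0L
  suppressed <- 0L
  candidates <- 0L
  while (n_acc < config$k_published) {
    candidates <- candidates + 1L
    if (candidates > 1e6L)
      stop("selection too severe: 10^6 candidates drawn without reaching ",
           config$k_published, " published studies", call. = FALSE)
    st <- simulate_study(config, study_id = "pending")
    if (apply_selection(wald_p(st$y, st$s), config)) {
      n_acc <- n_acc + 1L
      st$study_id <- sprintf("%s_s%02d", meta_id, n_acc)
      accepted[[n_acc]] <- st
    } else {
      suppressed <- suppressed + 1L
    }
  }
  out <- dplyr::bind_rows(accepted)
  out <- tibble::tibble(meta_id = meta_id,
                        research_area = config$research_area,
                        exposure = "synthetic_exposure",
                        outcome = "all_cause_mortality",
                        out[, c("study_id", "effect", "ci_lower",
                                "ci_upper", "measure", "n_participants",
                                "n_deaths")])
  attr(out, "suppressed") <- suppressed
  out
}

#' Generate a synthetic corpus
#'
#' `n_metas` independent meta-analyses, each generated from its own
#' sub-stream derived from `config$seed`, so corpora are reproducible and
#' insensitive to generation order. The result is a valid `bias_corpus`
#' that round-trips through [write_corpus()]/[read_corpus()].
#'
#' @param config A [synthetic_config()] with `n_metas >= 1`.
#' @return A `bias_corpus` with attribute `suppressed` (per-meta counts).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$n_metas < 1L)
    stop("n_metas must be at least 1 to generate a corpus", call. = FALSE)
  subseeds <- derive_subseeds(config$seed, config$n_metas)
  metas <- vector("list", config$n_metas)
  suppressed <- integer(config$n_metas)
  for (i in seq_len(config$n_metas)) {
    set.seed(subseeds[i])
    metas[[i]] <- generate_meta(config, meta_id = sprintf("meta_%03d", i))
    suppressed[i] <- attr(metas[[i]], "suppressed")
  }
  out <- as_corpus(dplyr::bind_rows(metas))
  attr(out, "suppressed") <- suppressed
  out
}

#' Operating characteristics of the bias tests under a known truth
#'
#' Simulates `reps` meta-analyses from `config`, runs the Egger and
#' excess-significance tests on each, and reports flag rates with
#' Monte-Carlo standard errors, plus the mean observed and expected
#' significant-study counts. Under the no-selection null
#' (`theta = 0, tau = 0, p_publish_nonsig = 1`) the Egger flag rate
#' estimates the test's size at its 0.10 threshold and `mean_O / k`
#' estimates the per-study size 0.05.
#'
#' @param config A [synthetic_config()].
#' @param reps Number of simulated meta-analyses, `>= 100`.
#' @return A list of class `operating_characteristics`: `reps`,
#'   `egger_flag_rate`, `excess_flag_rate`, `mean_O`, `mean_E`,
#'   `mc_se_egger`, `mc_se_excess`, `mc_se_O`, `mc_se_E`.
#' @export
operating_characteristics <- function(config, reps = 1000L) {
  stopifnot(inherits(config, "synthetic_config"), reps >= 100L)
  subseeds <- derive_subseeds(config$seed, reps)
  egger_flags <- logical(reps)
  excess_flags <- logical(reps)
  O <- integer(reps)
  E <- numeric(reps)
  for (r in seq_len(reps)) {
    set.seed(subseeds[r])
    meta <- generate_meta(config, meta_id = sprintf("rep_%05d", r))
    ls <- study_log_stats(meta$effect, meta$ci_lower, meta$ci_upper)
    eg <- egger_test(ls$y, ls$s)
    egger_flags[r] <- eg$eligible && eg$flagged
    ex <- excess_significance_test(ls$y, ls$s)
    excess_flags[r] <- ex$eligible && ex$flagged
    O[r] <- ex$observed
    E[r] <- ex$expected
  }
  rate_se <- function(r) sqrt(r * (1 - r) / reps)
  structure(
    list(reps = as.integer(reps),
         egger_flag_rate = mean(egger_flags),
         excess_flag_rate = mean(excess_flags),
         mean_O = mean(O), mean_E = mean(E),
         mc_se_egger = rate_se(mean(egger_flags)),
         mc_se_excess = rate_se(mean(excess_flags)),
         mc_se_O = stats::sd(O) / sqrt(reps),
         mc_se_E = stats::sd(E) / sqrt(reps)),
    class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Operating characteristics over %d simulated meta-analyses\n",
              x$reps))
  cat(sprintf("  Egger flag rate:  %.3f (MC SE %.3f)\n",
              x$egger_flag_rate, x$mc_se_egger))
  cat(sprintf("  excess flag rate: %.3f (MC SE %.3f)\n",
              x$excess_flag_rate, x$mc_se_excess))
  cat(sprintf("  mean O = %.3f (SE %.3f), mean E = %.3f (SE %.3f)\n",
              x$mean_O, x$mc_se_O, x$mean_E, x$mc_se_E))
  invisible(x)
}
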