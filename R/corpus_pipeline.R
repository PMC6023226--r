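# Corpus-level orchestration: run every meta-analysis through pooling and
# both bias tests, apply eligibility/sensitivity filters, tabulate by
# research area, and tally ROBIS judgments.

#' Configuration for a corpus audit
#'
#' Bundles the audit's thresholds: the minimum number of primary studies
#' for the bias tests (3), the Egger flagging level (two-sided p < 0.10),
#' the excess-significance flagging level (two-sided p < 0.10, i.e.
#' one-sided 0.05 for O > E), the per-study significance level (0.05), and
#' the two sensitivity-filter cutoffs (>= 10 studies; >= 200 deaths).
#' All p-value comparisons downstream are strict (`<`).
#'
#' @param min_k_tests Minimum studies for Egger/excess eligibility (`>= 3`).
#' @param egger_alpha Two-sided Egger flagging threshold.
#' @param excess_alpha Two-sided excess-significance flagging threshold.
#' @param study_alpha Per-study significance level for O, E and pooled
#'   significance.
#' @param sensitivity_min_k Study-count cutoff for [sensitivity_min_k()].
#' @param min_deaths Death-count cutoff for [sensitivity_exclude_small()].
#' @param direction How primary-study significance is counted; see
#'   [observed_significant()].
#' @return A list of class `audit_config`.
#' @export
audit_config <- function(min_k_tests = 3L, egger_alpha = 0.10,
                         excess_alpha = 0.10, study_alpha = 0.05,
                         sensitivity_min_k = 10L, min_deaths = 200L,
                         direction = c("either", "theta")) {
  direction <- match.arg(direction)
  for (a in c(egger_alpha, excess_alpha, study_alpha))
    if (!is.finite(a) || a <= 0 || a >= 1)
      stop("significance levels must lie in (0, 1)", call. = FALSE)
  if (min_k_tests < 3L)
    stop("min_k_tests must be at least 3", call. = FALSE)
  structure(list(min_k_tests = as.integer(min_k_tests),
                 egger_alpha = egger_alpha, excess_alpha = excess_alpha,
                 study_alpha = study_alpha,
                 sensitivity_min_k = as.integer(sensitivity_min_k),
                 min_deaths = as.integer(min_deaths),
                 direction = direction),
            class = "audit_config")
}

empty_corpus <- function() {
  out <- tibble::as_tibble(as.data.frame(
    matrix(nrow = 0, ncol = length(.corpus_cols),
           dimnames = list(NULL, .corpus_cols))))
  class(out) <- c("bias_corpus", class(out))
  out
}

#' Keep only meta-analyses with at least `min_k` primary studies
#'
#' The bias tests have low power in small meta-analyses, so the audit is
#' re-run on the subsample of larger ones (conventionally `k >= 10`).
#'
#' @param corpus A `bias_corpus`.
#' @param min_k Minimum study count, `>= 1`.
#' @return A filtered `bias_corpus`; the input is not modified. Empty (with
#'   a warning) when no meta-analysis qualifies.
#' @export
sensitivity_min_k <- function(corpus, min_k = 10L) {
  stopifnot(inherits(corpus, "bias_corpus"), min_k >= 1L)
  k_by_meta <- table(corpus$meta_id)
  keep <- names(k_by_meta)[k_by_meta >= min_k]
  out <- corpus[corpus$meta_id %in% keep, ]
  if (nrow(out) == 0L) {
    warning("no meta-analysis has at least ", min_k,
            " studies; corpus is empty", call. = FALSE)
    return(empty_corpus())
  }
  out
}

#' Drop small primary studies (by death count) from a corpus
#'
#' Removes studies with a known death count below `min_deaths`; studies
#' with missing death counts cannot be filtered and are retained with a
#' warning. Meta-analyses left with fewer than 2 studies are dropped; their
#' ids are recorded in the `dropped_metas` attribute.
#'
#' @param corpus A `bias_corpus`.
#' @param min_deaths Minimum deaths, `>= 0`.
#' @return A filtered `bias_corpus` with attribute `dropped_metas`.
#' @export
sensitivity_exclude_small <- function(corpus, min_deaths = 200L) {
  stopifnot(inherits(corpus, "bias_corpus"), min_deaths >= 0L)
  if (min_deaths == 0L) {
    attr(corpus, "dropped_metas") <- character(0)
    return(corpus)
  }
  unknown <- is.na(corpus$n_deaths)
  if (any(unknown))
    warning(sum(unknown), " studies with missing death counts retained ",
            "(cannot apply the <", min_deaths, "-deaths filter)",
            call. = FALSE)
  out <- corpus[unknown | corpus$n_deaths >= min_deaths, ]
  k_by_meta <- table(out$meta_id)
  dropped <- names(k_by_meta)[k_by_meta < 2L]
  dropped <- c(dropped, setdiff(unique(corpus$meta_id), names(k_by_meta)))
  out <- out[!out$meta_id %in% dropped, ]
  if (nrow(out) == 0L) {
    warning("no meta-analysis retains at least 2 studies after removing ",
            "studies with fewer than ", min_deaths, " deaths",
            call. = FALSE)
    out <- empty_corpus()
  }
  attr(out, "dropped_metas") <- dropped
  out
}

#' Audit a corpus of meta-analyses for reporting bias
#'
#' For every meta-analysis in the corpus: re-pool with the random-effects
#' model ([pool_random_effects()], needs `k >= 2`), then run the Egger
#' small-study-effect test and the excess-significance test where
#' `k >= min_k_tests`. Eligibility and exclusions are recorded per
#' meta-analysis, and the per-area summary (one row per research area plus
#' an overall row) is assembled with [tabulate_by_area()]. The audit is
#' fully deterministic.
#'
#' @param corpus A `bias_corpus`.
#' @param config An [audit_config()].
#' @return A list of class `bias_audit` with elements `per_meta` (tibble,
#'   one row per meta-analysis), `area_summary` (tibble), `config`, and
#'   `log` (exclusions and notes, machine-readable).
#' @export
run_audit <- function(corpus, config = audit_config()) {
  stopifnot(inherits(corpus, "bias_corpus"),
            inherits(config, "audit_config"))
  if (nrow(corpus) == 0L)
    stop("cannot audit an empty corpus", call. = FALSE)

  meta_ids <- unique(corpus$meta_id)
  exclusions <- list()
  rows <- vector("list", length(meta_ids))

  for (i in seq_along(meta_ids)) {
    id <- meta_ids[i]
    sub <- corpus[corpus$meta_id == id, ]
    ls <- study_log_stats(sub$effect, sub$ci_lower, sub$ci_upper)
    k <- nrow(sub)
    row <- tibble::tibble(
      meta_id = id, research_area = sub$research_area[1],
      exposure = sub$exposure[1], outcome = sub$outcome[1], k = k,
      pooled = k >= 2L,
      pooled_effect_ratio = NA_real_, ci_lower = NA_real_,
      ci_upper = NA_real_, p_value = NA_real_, q = NA_real_,
      tau2 = NA_real_, i2 = NA_real_, sig = NA,
      egger_eligible = FALSE, egger_intercept = NA_real_,
      egger_se = NA_real_, egger_p = NA_real_, egger_flag = FALSE,
      excess_eligible = FALSE, O = NA_integer_, E = NA_real_,
      theta_star_ratio = NA_real_, chi2 = NA_real_,
      excess_p = NA_real_, o_gt_e = FALSE, excess_flag = FALSE)

    if (k < 2L) {
      exclusions <- c(exclusions, list(list(
        meta_id = id, reason = "fewer_than_2_studies")))
      rows[[i]] <- row
      next
    }
    pr <- pool_random_effects(ls$y, ls$s)
    row$pooled_effect_ratio <- exp(pr$y_pooled)
    row$ci_lower <- exp(pr$ci_lower)
    row$ci_upper <- exp(pr$ci_upper)
    row$p_value <- pr$p_value
    row$q <- pr$q_stat
    row$tau2 <- pr$tau2
    row$i2 <- pr$i2
    row$sig <- pr$p_value < config$study_alpha

    if (k >= config$min_k_tests) {
      eg <- tryCatch(egger_test(ls$y, ls$s, alpha = config$egger_alpha),
                     error = function(e) e)
      if (inherits(eg, "error")) {
        exclusions <- c(exclusions, list(list(
          meta_id = id, reason = "egger_degenerate_design")))
      } else if (eg$eligible) {
        row$egger_eligible <- TRUE
        row$egger_intercept <- eg$intercept
        row$egger_se <- eg$intercept_se
        row$egger_p <- eg$p_two_sided
        row$egger_flag <- eg$flagged
      }
      ex <- excess_significance_test(ls$y, ls$s,
                                     alpha_study = config$study_alpha,
                                     alpha_test = config$excess_alpha,
                                     direction = config$direction)
      if (ex$eligible) {
        row$excess_eligible <- TRUE
        row$O <- ex$observed
        row$E <- ex$expected
        row$theta_star_ratio <- exp(ex$theta_star)
        row$chi2 <- ex$chi2
        row$excess_p <- ex$p_value
        row$o_gt_e <- ex$o_gt_e
        row$excess_flag <- ex$flagged
      }
    } else {
      exclusions <- c(exclusions, list(list(
        meta_id = id, reason = "fewer_than_min_k_tests")))
    }
    rows[[i]] <- row
  }

  per_meta <- dplyr::bind_rows(rows)
  structure(
    list(per_meta = per_meta,
         area_summary = tabulate_by_area(per_meta),
         config = config,
         log = list(exclusions = exclusions,
                    n_metas = length(meta_ids),
                    n_pooled = sum(per_meta$pooled),
                    note = paste("all meta-analyses re-pooled with the",
                                 "DerSimonian-Laird random-effects model"))),
    class = "bias_audit")
}

round_half_up <- function(x) floor(x + 0.5)

pct <- function(n, d) {
  d <- rep(d, length.out = length(n))
  out <- round_half_up(100 * n / d)
  out[d <= 0] <- NA_real_
  out
}

#' Tabulate audit results by research area
#'
#' Builds the per-area frequency table: number of pooled meta-analyses,
#' number and percent with a significant pooled effect, Egger-eligible
#' count/flags/percent, and excess-significance eligibility, O > E counts
#' and flags. Percents are integers (round half up), each over its own
#' eligible denominator; raw proportions are emitted alongside. A final
#' `overall` row sums the area rows. Only pooled meta-analyses (`k >= 2`)
#' enter any denominator.
#'
#' @param per_meta The `per_meta` tibble from [run_audit()].
#' @return A tibble, one row per research area present plus `overall`.
#' @export
tabulate_by_area <- function(per_meta) {
  stopifnot(is.data.frame(per_meta), nrow(per_meta) > 0)
  bad <- !per_meta$research_area %in% research_areas()
  if (any(bad))
    stop("unknown research_area ",
         sQuote(per_meta$research_area[bad][1]), call. = FALSE)
  pm <- per_meta[per_meta$pooled, ]
  pm$research_area <- factor(pm$research_area,
                             levels = research_areas())
  sums <- pm |>
    dplyr::group_by(research_area, .drop = TRUE) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_sig = sum(sig, na.rm = TRUE),
      n_egger_eligible = sum(egger_eligible),
      n_egger_flag = sum(egger_flag),
      n_excess_eligible = sum(excess_eligible),
      n_o_gt_e = sum(o_gt_e),
      n_excess_flag = sum(excess_flag),
      .groups = "drop") |>
    dplyr::mutate(research_area = as.character(research_area))
  overall <- sums |>
    dplyr::summarise(dplyr::across(dplyr::where(is.numeric), sum)) |>
    dplyr::mutate(research_area = "overall", .before = 1)
  out <- dplyr::bind_rows(sums, overall) |>
    dplyr::mutate(
      pct_sig = pct(n_sig, n_total),
      pct_egger = pct(n_egger_flag, n_egger_eligible),
      pct_o_gt_e = pct(n_o_gt_e, n_excess_eligible),
      pct_excess = pct(n_excess_flag, n_excess_eligible),
      pct_excess_of_ogt = pct(n_excess_flag, n_o_gt_e),
      prop_sig = n_sig / n_total,
      prop_egger = ifelse(n_egger_eligible > 0,
                          n_egger_flag / n_egger_eligible, NA_real_),
      prop_excess = ifelse(n_excess_eligible > 0,
                           n_excess_flag / n_excess_eligible, NA_real_))
  dplyr::select(out, research_area, n_total, n_sig, pct_sig,
                n_egger_eligible, n_egger_flag, pct_egger,
                n_excess_eligible, n_o_gt_e, pct_o_gt_e,
                n_excess_flag, pct_excess, pct_excess_of_ogt,
                prop_sig, prop_egger, prop_excess)
}

#' Tally ROBIS judgments by domain and research area
#'
#' Counts and percents of low/high/unclear judgments for each of the four
#' ROBIS domains and (when recorded) the overall phase-3 judgment, both
#' across all reviews (`research_area = "overall"`) and within each
#' research area. Long format, suitable for stacked-bar plotting.
#'
#' @param robis A `robis_set` from [read_robis()] / [as_robis()].
#' @return A tibble of class `robis_summary` with columns `research_area`,
#'   `domain` (`d1`..`d4`, `overall`), `judgment`, `n`, `pct` and
#'   `n_reviews` (the denominator).
#' @export
robis_tabulate <- function(robis) {
  stopifnot(inherits(robis, "robis_set"), nrow(robis) > 0)
  domains <- c("d1", "d2", "d3", "d4", "overall")
  tally_block <- function(df, area_label) {
    blocks <- lapply(domains, function(d) {
      vals <- df[[d]]
      if (d == "overall" && all(is.na(vals))) return(NULL)
      n <- vapply(.judgments, function(j) sum(vals == j, na.rm = TRUE),
                  integer(1))
      tibble::tibble(research_area = area_label, domain = d,
                     judgment = .judgments, n = as.integer(n),
                     pct = pct(n, sum(n)), n_reviews = sum(n))
    })
    dplyr::bind_rows(blocks)
  }
  out <- dplyr::bind_rows(
    tally_block(robis, "overall"),
    dplyr::bind_rows(lapply(
      intersect(research_areas(), unique(robis$research_area)),
      function(a) tally_block(robis[robis$research_area == a, ], a))))
  class(out) <- c("robis_summary", class(out))
  out
}

#' Write audit outputs to a directory
#'
#' Writes `per_meta.csv`, `area_summary.csv`, `robis_summary.csv` (header
#' only when no ROBIS summary is supplied) and `run_log.json` (config,
#' package version, eligibility decisions). Output is deterministic: a
#' rerun on the same inputs produces byte-identical files.
#'
#' @param audit A `bias_audit` from [run_audit()].
#' @param dir Output directory, created if needed.
#' @param robis_summary Optional `robis_summary` from [robis_tabulate()].
#' @return Character vector of the four file paths, invisibly.
#' @export
write_report <- function(audit, dir, robis_summary = NULL) {
  stopifnot(inherits(audit, "bias_audit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("per_meta.csv", "area_summary.csv",
                            "robis_summary.csv", "run_log.json"))
  utils::write.csv(audit$per_meta, paths[1], row.names = FALSE, na = "")
  utils::write.csv(audit$area_summary, paths[2], row.names = FALSE, na = "")
  if (is.null(robis_summary)) {
    writeLines("research_area,domain,judgment,n,pct,n_reviews", paths[3])
  } else {
    utils::write.csv(as.data.frame(robis_summary), paths[3],
                     row.names = FALSE, na = "")
  }
  log <- list(package = "biasaudit",
              version = as.character(utils::packageVersion("biasaudit")),
              config = unclass(audit$config),
              log = audit$log)
  jsonlite::write_json(log, paths[4], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(paths)
}
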