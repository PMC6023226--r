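# Study-level data: effect-scale conversions, corpus and ROBIS readers/writers.

#' Research areas recognized by the audit
#'
#' The six literatures covered by the audit: five health-related behaviors
#' (observational evidence) plus statins in primary prevention (trial
#' evidence), all with cardiovascular or all-cause mortality outcomes.
#'
#' @return Character vector of valid `research_area` labels.
#' @export
research_areas <- function() {
  c("physical_activity", "sedentary_behavior", "alcohol",
    "smoking", "diet", "statin")
}

.judgments <- c("low", "high", "unclear")
.measures <- c("RR", "OR", "HR", "other")

#' Standard error of a log ratio from its confidence interval
#'
#' Back-calculates the standard error of a log relative effect (log RR/OR/HR)
#' from the ratio-scale confidence interval bounds:
#' \eqn{s = (\log U - \log L) / (2 z_{(1+level)/2})}.
#'
#' @param lower,upper Ratio-scale confidence bounds, both `> 0`,
#'   `lower < upper`. Vectorized.
#' @param level Confidence level as a proportion in (0, 1); default `0.95`
#'   (for which the normal quantile is 1.959964).
#' @return Standard error(s) on the natural-log scale, positive and finite.
#' @examples
#' se_from_ci(1.0, 4.0)            # 0.35366
#' se_from_ci(0.5, 2.0)            # identical, by log-symmetry
#' @export
se_from_ci <- function(lower, upper, level = 0.95) {
  if (length(level) == 1L) level <- rep(level, length(lower))
  stopifnot(length(lower) == length(upper), length(level) == length(lower))
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("confidence bounds must be finite", call. = FALSE)
  if (any(lower <= 0) || any(upper <= 0))
    stop("confidence bounds must be positive (ratio scale)", call. = FALSE)
  if (any(lower >= upper))
    stop("ci_lower must be strictly below ci_upper", call. = FALSE)
  if (any(level <= 0) || any(level >= 1))
    stop("ci_level must lie in (0, 1)", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  (log(upper) - log(lower)) / (2 * z)
}

#' Log-scale effect and standard error for primary studies
#'
#' Converts ratio-scale point estimates and confidence intervals to the
#' (y, s) pairs all downstream statistics operate on: `y = log(effect)` and
#' `s` back-calculated from the interval via [se_from_ci()]. The point
#' estimate must lie inside the interval after widening the bounds by 1%
#' relative slack, tolerating published rounding.
#'
#' @param effect Ratio-scale point estimate(s), `> 0`.
#' @param ci_lower,ci_upper Ratio-scale 95% (or `level`) bounds.
#' @param level Confidence level, default `0.95`.
#' @return A data.frame with columns `y` (log effect) and `s` (its SE).
#' @examples
#' study_log_stats(2.0, 1.0, 4.0)  # y = log 2, s = 0.35366
#' @export
study_log_stats <- function(effect, ci_lower, ci_upper, level = 0.95) {
  if (any(!is.finite(effect)) || any(effect <= 0))
    stop("effect estimates must be positive and finite (ratio scale)",
         call. = FALSE)
  s <- se_from_ci(ci_lower, ci_upper, level)
  outside <- effect < ci_lower * 0.99 | effect > ci_upper * 1.01
  if (any(outside))
    stop("effect estimate outside its confidence interval ",
         "(beyond 1% rounding slack) at position(s) ",
         paste(which(outside), collapse = ", "), call. = FALSE)
  data.frame(y = log(effect), s = s)
}

.corpus_cols <- c("meta_id", "research_area", "exposure", "outcome",
                  "study_id", "effect", "ci_lower", "ci_upper", "measure",
                  "n_participants", "n_deaths")

#' Validate and classify a study-level corpus table
#'
#' A corpus is a data frame with one row per primary study, grouped into
#' meta-analyses by `meta_id`, using the column schema of [read_corpus()].
#' Validation enforces: positive effects and bounds, `ci_lower < ci_upper`,
#' point estimate inside the (1%-widened) interval, recognized research
#' areas and effect measures, unique `study_id` within each `meta_id`, and
#' a single research area/exposure/outcome per `meta_id`.
#'
#' @param df A data.frame with the corpus columns.
#' @return The validated corpus as a tibble of class `bias_corpus`.
#' @export
as_corpus <- function(df) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(.corpus_cols, names(df))
  if (length(missing_cols))
    stop("corpus is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("corpus contains no studies", call. = FALSE)
  df <- df[, .corpus_cols]
  for (col in c("effect", "ci_lower", "ci_upper"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("n_participants", "n_deaths"))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))

  bad_area <- !df$research_area %in% research_areas()
  if (any(bad_area))
    stop("unknown research_area ", sQuote(df$research_area[bad_area][1]),
         " for meta_id ", sQuote(df$meta_id[bad_area][1]), call. = FALSE)
  bad_measure <- !df$measure %in% .measures
  if (any(bad_measure))
    stop("unknown measure ", sQuote(df$measure[bad_measure][1]),
         "; expected one of ", paste(.measures, collapse = ", "),
         call. = FALSE)

  for (i in seq_len(nrow(df))) {
    ok <- tryCatch({
      study_log_stats(df$effect[i], df$ci_lower[i], df$ci_upper[i])
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("invalid study ", sQuote(df$study_id[i]), " in meta-analysis ",
           sQuote(df$meta_id[i]), ": ", conditionMessage(ok), call. = FALSE)
    for (col in c("n_participants", "n_deaths")) {
      v <- df[[col]][i]
      if (!is.na(v) && v < 0)
        stop("negative ", col, " for study ", sQuote(df$study_id[i]),
             " in meta-analysis ", sQuote(df$meta_id[i]), call. = FALSE)
    }
  }

  dup <- duplicated(df[, c("meta_id", "study_id")])
  if (any(dup))
    stop("duplicate study_id ", sQuote(df$study_id[dup][1]),
         " within meta-analysis ", sQuote(df$meta_id[dup][1]), call. = FALSE)
  n_area <- tapply(df$research_area, df$meta_id,
                   function(x) length(unique(x)))
  if (any(n_area > 1))
    stop("meta-analysis ", sQuote(names(n_area)[n_area > 1][1]),
         " spans more than one research_area", call. = FALSE)

  out <- tibble::as_tibble(df)
  class(out) <- c("bias_corpus", class(out))
  out
}

#' Read a study-level corpus CSV
#'
#' Expects a UTF-8, comma-separated file with a header row and columns
#' `meta_id, research_area, exposure, outcome, study_id, effect, ci_lower,
#' ci_upper, measure, n_participants, n_deaths`. Each row is one primary
#' study; rows sharing a `meta_id` form one meta-analysis, in file order.
#' Missing participant/death counts are allowed (empty cells or `NA`).
#'
#' @param path Path to the CSV file.
#' @return A validated `bias_corpus` tibble (see [as_corpus()]).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path))
    stop("corpus file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L)
    stop("empty corpus: ", path, " contains a header but no studies",
         call. = FALSE)
  as_corpus(df)
}

#' Write a corpus to CSV
#'
#' Inverse of [read_corpus()]; a written corpus re-reads to an identical
#' object.
#'
#' @param corpus A `bias_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "bias_corpus"))
  utils::write.csv(as.data.frame(corpus)[, .corpus_cols], path,
                   row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read ROBIS judgments for a set of systematic reviews
#'
#' ROBIS scores each review on four review-process domains — (1) study
#' eligibility criteria, (2) identification and selection of studies,
#' (3) data collection and study appraisal, (4) synthesis and findings —
#' plus an overall phase-3 judgment, each as low/high/unclear risk of bias.
#' Expected columns: `review_id, research_area, d1, d2, d3, d4, overall`.
#' Judgment tokens are normalized case-insensitively, and decorations such
#' as "low risk" are accepted. The `overall` column may be absent or blank
#' (some published tables print only the domain judgments); it is then
#' recorded as `NA`. Overall judgments are always consumed as data — ROBIS
#' phase 3 is a human judgment, never recomputed from the domains.
#'
#' @param path Path to the ROBIS CSV.
#' @return A tibble of class `robis_set`, one row per review.
#' @export
read_robis <- function(path) {
  if (!file.exists(path))
    stop("ROBIS file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_robis(df)
}

#' @rdname read_robis
#' @param df A data.frame with the ROBIS columns.
#' @export
as_robis <- function(df) {
  df <- as.data.frame(df)
  required <- c("review_id", "research_area", "d1", "d2", "d3", "d4")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("ROBIS table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"overall" %in% names(df)) df$overall <- NA_character_
  if (nrow(df) == 0L)
    stop("ROBIS table contains no reviews", call. = FALSE)
  if (anyDuplicated(df$review_id))
    stop("duplicate review_id: ",
         sQuote(df$review_id[duplicated(df$review_id)][1]), call. = FALSE)
  bad_area <- !df$research_area %in% research_areas()
  if (any(bad_area))
    stop("unknown research_area ", sQuote(df$research_area[bad_area][1]),
         " for review ", sQuote(df$review_id[bad_area][1]), call. = FALSE)
  for (col in c("d1", "d2", "d3", "d4", "overall")) {
    df[[col]] <- normalize_judgment(df[[col]], col = col,
                                    review_id = df$review_id,
                                    allow_na = col == "overall")
  }
  out <- tibble::as_tibble(df[, c(required, "overall")])
  class(out) <- c("robis_set", class(out))
  out
}

# "Low Risk" / " HIGH risk " / "unclear" -> canonical token; NA handling for
# the optional overall column only.
normalize_judgment <- function(x, col, review_id, allow_na = FALSE) {
  raw <- trimws(tolower(as.character(x)))
  raw <- sub("[[:space:]]+risk$", "", raw)
  blank <- is.na(raw) | raw == "" | raw == "na"
  if (any(blank) && !allow_na)
    stop("missing ", col, " judgment for review ",
         sQuote(review_id[blank][1]), call. = FALSE)
  bad <- !blank & !raw %in% .judgments
  if (any(bad))
    stop("unknown ", col, " judgment ", sQuote(as.character(x)[bad][1]),
         " for review ", sQuote(review_id[bad][1]),
         "; expected low/high/unclear", call. = FALSE)
  raw[blank] <- NA_character_
  raw
}
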