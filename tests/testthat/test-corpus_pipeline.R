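test_that("audit config validates its thresholds", {
  cfg <- audit_config()
  expect_equal(cfg$min_k_tests, 3L)
  expect_equal(cfg$egger_alpha, 0.10)
  expect_equal(cfg$study_alpha, 0.05)
  expect_equal(cfg$sensitivity_min_k, 10L)
  expect_equal(cfg$min_deaths, 200L)
  expect_error(audit_config(min_k_tests = 2), "at least 3")
  expect_error(audit_config(egger_alpha = 1.2), "\\(0, 1\\)")
})

test_that("run_audit pools, tests and records eligibility per meta", {
  corpus <- as_corpus(toy_corpus_df())
  audit <- run_audit(corpus)
  pm <- audit$per_meta
  expect_equal(nrow(pm), 3)
  # pa1 (k=5): pooled + both tests
  pa1 <- pm[pm$meta_id == "pa1", ]
  expect_true(pa1$pooled && pa1$egger_eligible && pa1$excess_eligible)
  expect_equal(pa1$k, 5)
  # pa2 (k=2): pooled only, tests ineligible
  pa2 <- pm[pm$meta_id == "pa2", ]
  expect_true(pa2$pooled)
  expect_false(pa2$egger_eligible || pa2$excess_eligible)
  reasons <- vapply(audit$log$exclusions, `[[`, "", "reason")
  expect_true("fewer_than_min_k_tests" %in% reasons)

  # per-meta pooled values match the engine directly
  sub <- corpus[corpus$meta_id == "pa1", ]
  ls <- study_log_stats(sub$effect, sub$ci_lower, sub$ci_upper)
  pr <- pool_random_effects(ls$y, ls$s)
  expect_equal(pa1$pooled_effect_ratio, exp(pr$y_pooled), tolerance = 1e-12)
  expect_equal(pa1$p_value, pr$p_value, tolerance = 1e-12)
  ex <- excess_significance_test(ls$y, ls$s)
  expect_equal(pa1$O, ex$observed)
  expect_equal(pa1$E, ex$expected, tolerance = 1e-12)
})

test_that("singleton meta-analyses are excluded from every denominator", {
  df <- toy_corpus_df()
  single <- df[1, ]
  single$meta_id <- "lone"
  single$study_id <- "only"
  audit <- run_audit(as_corpus(rbind(df, single)))
  lone <- audit$per_meta[audit$per_meta$meta_id == "lone", ]
  expect_false(lone$pooled)
  expect_true(is.na(lone$p_value))
  reasons <- vapply(audit$log$exclusions, `[[`, "", "reason")
  expect_true("fewer_than_2_studies" %in% reasons)
  # area totals unchanged by the unpoolable meta
  base <- run_audit(as_corpus(df))
  expect_equal(audit$area_summary$n_total, base$area_summary$n_total)
})

test_that("area tabulation adds up and recomputes percents exactly", {
  cfg <- synthetic_config(seed = 20, n_metas = 12, k_published = 6,
                          p_publish_nonsig = 0.3, theta = 0, tau = 0.1)
  audit <- run_audit(generate_corpus(cfg))
  tab <- audit$area_summary
  areas <- tab[tab$research_area != "overall", ]
  overall <- tab[tab$research_area == "overall", ]
  for (col in c("n_total", "n_sig", "n_egger_eligible", "n_egger_flag",
                "n_excess_eligible", "n_o_gt_e", "n_excess_flag"))
    expect_equal(overall[[col]], sum(areas[[col]]))
  # eligibility monotonicity
  expect_true(all(tab$n_excess_flag <= tab$n_o_gt_e))
  expect_true(all(tab$n_o_gt_e <= tab$n_excess_eligible))
  expect_true(all(tab$n_egger_flag <= tab$n_egger_eligible))
  expect_true(all(tab$n_excess_eligible <= tab$n_total))
  # percent cells recompute from count cells under round-half-up
  expect_equal(tab$pct_sig, floor(100 * tab$n_sig / tab$n_total + 0.5))
  ok <- tab$n_egger_eligible > 0
  expect_equal(tab$pct_egger[ok],
               floor(100 * tab$n_egger_flag[ok] /
                       tab$n_egger_eligible[ok] + 0.5))
})

test_that("min-k sensitivity filter keeps only large meta-analyses", {
  corpus <- as_corpus(toy_corpus_df())
  kept <- sensitivity_min_k(corpus, 4)
  expect_setequal(unique(kept$meta_id), c("pa1", "diet1"))
  expect_identical(as.data.frame(sensitivity_min_k(corpus, 1)),
                   as.data.frame(corpus))
  expect_warning(out <- sensitivity_min_k(corpus, 50), "empty")
  expect_equal(nrow(out), 0)
  # original untouched
  expect_equal(nrow(corpus), 11)
})

test_that("small-study exclusion drops by deaths and prunes tiny metas", {
  corpus <- as_corpus(toy_corpus_df())
  expect_warning(out <- sensitivity_exclude_small(corpus, 200),
                 "missing death counts")
  # pa1: deaths 250,120,80,500,90 -> keeps 250,500 (k=2)
  expect_equal(sum(out$meta_id == "pa1"), 2)
  # pa2: 400,600 both kept
  expect_equal(sum(out$meta_id == "pa2"), 2)
  # diet1: 210,150,800,NA -> 210,800 + NA retained (k=3)
  expect_equal(sum(out$meta_id == "diet1"), 3)
  expect_true("u4" %in% out$study_id)  # missing deaths retained
  # identity at zero
  out0 <- sensitivity_exclude_small(corpus, 0)
  expect_equal(as.data.frame(out0), as.data.frame(corpus),
               ignore_attr = TRUE)
  # metas reduced below 2 studies are dropped and reported; diet1 keeps
  # its 800-death study plus the missing-deaths one (retained) so survives
  expect_warning(strict <- sensitivity_exclude_small(corpus, 450),
                 "missing death counts")
  expect_false("pa1" %in% strict$meta_id)   # only the 500-death study left
  expect_false("pa2" %in% strict$meta_id)   # only the 600-death study left
  expect_setequal(attr(strict, "dropped_metas"), c("pa1", "pa2"))
  expect_equal(sum(strict$meta_id == "diet1"), 2)
})

test_that("ROBIS tabulation counts judgments per domain and area", {
  robis <- read_robis(robis_fixture_path())
  tally <- robis_tabulate(robis)
  g <- function(area, dom, jud)
    tally$n[tally$research_area == area & tally$domain == dom &
              tally$judgment == jud]
  # overall distributions across the 49 reviews
  expect_equal(g("overall", "d1", "low"), 32L)
  expect_equal(g("overall", "d2", "high"), 40L)
  expect_equal(g("overall", "d2", "low"), 7L)
  expect_equal(g("overall", "d2", "unclear"), 2L)
  expect_equal(g("overall", "d3", "high"), 28L)
  expect_equal(g("overall", "d3", "low"), 14L)
  expect_equal(g("overall", "d4", "high"), 30L)
  expect_equal(g("overall", "d4", "low"), 17L)
  # counts per area x domain sum to the area's review count
  for (a in unique(robis$research_area)) {
    n_area <- sum(robis$research_area == a)
    for (d in paste0("d", 1:4))
      expect_equal(sum(tally$n[tally$research_area == a &
                                 tally$domain == d]), n_area)
  }
  # all-low input tallies 100% low
  all_low <- as_robis(data.frame(
    review_id = c("r1", "r2"), research_area = "diet",
    d1 = "low", d2 = "low", d3 = "low", d4 = "low", overall = "low"))
  tl <- robis_tabulate(all_low)
  expect_true(all(tl$pct[tl$judgment == "low"] == 100))
  expect_true("overall" %in% tl$domain)  # overall judgment present here
})

test_that("report writing is deterministic and produces the four files", {
  cfg <- synthetic_config(seed = 31, n_metas = 5)
  audit <- run_audit(generate_corpus(cfg))
  robis <- robis_tabulate(read_robis(robis_fixture_path()))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_report(audit, d1, robis)
  p2 <- write_report(audit, d2, robis)
  expect_setequal(basename(p1), c("per_meta.csv", "area_summary.csv",
                                  "robis_summary.csv", "run_log.json"))
  expect_true(all(file.exists(p1)))
  for (i in seq_along(p1))
    expect_identical(readLines(p1[i]), readLines(p2[i]))
  # without a ROBIS summary the file is header-only
  d3 <- withr::local_tempdir()
  p3 <- write_report(audit, d3)
  expect_equal(length(readLines(p3[3])), 1L)
})
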