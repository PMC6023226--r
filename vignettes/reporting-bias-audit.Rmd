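---
title: "Auditing meta-analytic literatures for reporting bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing meta-analytic literatures for reporting bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biasaudit)
```

## The problem

Reporting bias — the selective publication or selective analysis of results
depending on their direction and significance — distorts what a body of
literature appears to say. Epidemiological literatures on health-related
behaviors (physical activity, sedentary behavior, alcohol, smoking, diet)
and cardiovascular or all-cause mortality are a prime setting: many small
observational studies, strong prior expectations, and meta-analyses that
inherit whatever selection shaped the primary literature. `biasaudit`
implements a corpus-level audit of such literatures: every meta-analysis in
a corpus is re-pooled from its primary studies and screened with two
complementary reporting-bias statistics, the results are tabulated by
research area, and ROBIS risk-of-bias judgments of the parent systematic
reviews are tallied alongside. A synthetic-corpus generator with a
publication-selection mechanism makes every stage testable with a known
truth and lets users measure the tests' operating characteristics.

## Data model

The unit of audit is the **corpus**: a CSV with one row per primary study,
grouped into meta-analyses by `meta_id`, each carrying a ratio-scale effect
estimate (RR, OR or HR), its 95% confidence interval, and optionally
participant and death counts. All statistics work on the natural-log scale:
for a study reporting effect $e$ with interval $(L, U)$ at level
$1-\alpha$,

$$y = \log e, \qquad s = \frac{\log U - \log L}{2\, z_{(1+\text{level})/2}},$$

with $z_{0.975} = 1.959964$ for a 95% interval. The three ratio measures
are treated identically on the log scale and are never converted into one
another: source meta-analyses pool them as reported, and the audit
reproduces that behavior rather than imposing a harmonization the original
syntheses did not perform. Non-95% intervals are supported through the
level argument of `study_log_stats()`, with 95% the default. Validation
allows the point estimate to sit up to 1% (relative) outside its printed
interval, since published values are rounded; beyond that the row is
rejected as inconsistent.

## Re-pooling: random-effects synthesis

Each meta-analysis with $k \ge 2$ studies is re-pooled with the
DerSimonian–Laird random-effects model. With fixed-effect weights
$w_i = 1/s_i^2$, Cochran's heterogeneity statistic is
$Q = \sum_i w_i (y_i - \hat y_F)^2$ about the fixed-effect mean, the
moment estimator of the between-study variance is

$$\hat\tau^2 = \max\!\left(0,\; \frac{Q - (k-1)}
  {\sum w_i - \sum w_i^2 / \sum w_i}\right),$$

and the pooled effect uses weights $w_i^* = 1/(s_i^2 + \hat\tau^2)$ with a
normal (z) confidence interval and two-sided Wald p-value.
$I^2 = 100\,\max(0, (Q - (k-1))/Q)$ summarizes heterogeneity as a
percentage; both $\hat\tau^2$ and $I^2$ are explicitly truncated at zero.

DerSimonian–Laird with a z reference was chosen over REML or
Knapp–Hartung because it is the default of the review software behind the
source literatures this audit targets; reproducing those defaults is the
point of re-pooling. Everything is re-pooled as random effects, including
any meta-analysis originally reported as fixed-effect — one consistent
model across the corpus, recorded in the run log.

## The two bias tests

**Small-study effect (Egger regression).** Smaller studies that only reach
print when their estimates are large leave an association between effect
size and standard error. The classic regression form fits, by ordinary
least squares, the standardized effect $y_i/s_i$ on precision $1/s_i$; the
intercept captures the asymmetry and is referred to a t distribution on
$k-2$ degrees of freedom. A meta-analysis is flagged at two-sided
$p < 0.10$, the conventional threshold for this low-powered test. At least
3 studies are required; smaller meta-analyses are recorded as ineligible
rather than errors so tabulation denominators stay honest. Identical
standard errors make the regressor constant and raise an error instead of
returning an arbitrary fit.

**Excess significance.** A literature can also betray selection by
containing more nominally significant studies than its power could
plausibly produce. The observed count $O$ is the number of studies with
two-sided Wald $p < 0.05$, recomputed from $y_i/s_i$ — published p-values
are not uniformly available, confidence intervals are. The expected count
is $E = \sum_i \pi_i$, where $\pi_i$ is the power of study $i$'s level-0.05
two-sided test under a plausible effect $\theta^*$:

$$\pi_i = 1 - \Phi\!\left(z_{0.975} - |\theta^*|/s_i\right)
        + \Phi\!\left(-z_{0.975} - |\theta^*|/s_i\right).$$

$\theta^*$ is the effect of the most precise study in the meta-analysis
(smallest $s_i$); precision ties break toward the effect closest to the
null, then input order — a conservative rule that can only shrink $E$'s
gap to $O$. $O$ and $E$ are compared with the binomial-type chi-square
$(O-E)^2/E + (O-E)^2/(k-E)$ on 1 df. The chi-square was preferred to a
binomial with averaged power because powers differ across studies; an
exact Poisson–binomial enumeration would cost $2^k$ and serves instead as
a verification oracle in the test suite, where the chi-square decision
agrees with it on well over 95% of random small instances. The flag
requires *both* $O > E$ and one-sided $p < 0.05$ (two-sided $p < 0.10$):
a deficit of significant studies is never evidence of excess. All
threshold comparisons are strict (`<`).

Two genuinely open choices are worth recording. First, whether $O$ counts
significance in either direction or only in $\theta^*$'s direction:
the default counts either direction, which matches recomputing
significance from the published interval alone; `direction = "theta"` is
available for the stricter reading. Second, eligibility: any meta-analysis
with $k \ge 3$ and valid intervals is considered able to support both
tests; per-meta eligibility and every exclusion reason are recorded
machine-readably in the run log, so alternative availability rules can be
applied downstream.

## Corpus pipeline and tabulation

`run_audit()` applies pooling and both tests to every meta-analysis,
records eligibility, and tabulates by research area: total and significant
pooled results, Egger-eligible counts and flags, excess-eligible counts,
$O > E$ counts and flags, plus an overall row that sums the areas. Only
meta-analyses with $k \ge 2$ enter any denominator. Percentages are
integers (round half up) over each column's own eligible denominator, with
raw proportions emitted alongside; the excess column additionally reports
flags as a share of the $O > E$ meta-analyses, since both bases are used
when such audits are summarized.

Two sensitivity filters address the tests' low power: restricting to
meta-analyses with at least 10 primary studies (`sensitivity_min_k()`),
and removing individual studies with fewer than 200 recorded deaths
(`sensitivity_exclude_small()`). Studies with missing death counts cannot
be filtered and are retained with a warning; meta-analyses reduced below 2
studies are dropped and named. When both filters are combined the pipeline
applies the study-level exclusion first, recounts $k$, then applies the
study-count cutoff, and logs that order rather than asserting the filters
commute.

ROBIS judgments (four review-process domains plus an overall phase-3
judgment, each low/high/unclear) are consumed strictly as data:
the overall judgment is a human synthesis that ROBIS requires and must
never be recomputed from the domains. The packaged 49-review assessment
table (`inst/extdata/robis_table1.csv`) carries the four domain columns;
its overall column is blank because the published per-review table prints
only the domains, and the reader treats a blank overall as missing rather
than inventing a value.

## The synthetic generator

`synthetic_config()` defines a normal–normal literature with a
file-drawer: per study, a standard error drawn log-uniformly from
$(s_{\min}, s_{\max})$ — producing the long-tailed study-size mix of real
funnel plots — a study-level true effect
$\theta_i \sim N(\theta, \tau^2)$, an estimate $y \sim N(\theta_i, s^2)$,
and a death count $\mathrm{round}(c/s^2)$ tying size to precision so the
death-count filter is exercisable ($c = 1$, an arbitrary documented
constant). Selection is the simplest file-drawer mechanism: a study
significant at the two-sided 0.05 level is always published, a
non-significant one with probability `p_publish_nonsig`; candidates are
drawn until the target number of published studies is reached, and the
number suppressed is recorded.

Defaults are fixed once to emulate a behavior–mortality literature:
9 studies per meta-analysis (the average in such corpora), a true relative
risk of 1.3, between-study SD $\tau = 0.15$ (moderate heterogeneity),
standard errors from 0.05 to 0.5, and no selection — selection strength is
the experimental variable, not a default. Each meta-analysis is generated
from its own sub-stream derived from the master seed, so corpora are
reproducible and order-insensitive.

What the generator does *not* emulate: survival-time structure,
correlated estimates from shared cohorts, dose–response designs, and the
empirical SE mix of any particular real corpus. Passing tests on
synthetic corpora therefore validate the statistics and the plumbing, not
the substantive conclusions one would draw from real literatures.

`operating_characteristics()` runs both tests over replicated synthetic
meta-analyses and reports flag rates with Monte-Carlo standard errors
$\sqrt{r(1-r)/\text{reps}}$. Three calibration facts, all checked in the
test suite at these problem sizes: under the null
($\theta = 0, \tau = 0$, no selection, $k = 20$, 2000 reps) the Egger
flag rate sits within $[0.07, 0.13]$ of its 0.10 level and mean $O/k$
within Monte-Carlo error of 0.05; the excess test is conservative (flag
rate well under its nominal 0.05, because the plausible-effect rule
re-estimates $\theta^*$ per replicate); and flag rates are non-decreasing
in selection severity over a `p_publish_nonsig` grid of 1/0.4/0.1 at 1000
reps. One subtlety: selection at the *null* truth publishes significant
studies of either sign, which inflates excess significance sharply but
creates little funnel asymmetry, so the Egger rate responds weakly there —
the two tests genuinely detect different footprints of selection.

## Numerical choices and degenerate inputs

- z-quantiles are computed (`qnorm`), never hard-coded; the documented
  95% value is 1.959964.
- $\hat\tau^2$ and $I^2$ truncate at 0; $I^2$ is defined 0 when $Q = 0$.
- An expected count at the boundary ($E = 0$ or $E = k$, reachable only at
  floating-point saturation) is clamped to $[10^{-9}k, (1-10^{-9})k]$
  before the chi-square, and the clamping is flagged in the result.
- Meta-analyses below the eligibility thresholds yield ineligible results,
  not errors; truly invalid inputs (nonpositive bounds, inverted
  intervals, duplicate ids) fail loudly at parse time with the offending
  meta/study named.
- Reruns are byte-identical: no timestamps in outputs, all randomness
  seeded, report files written deterministically.

## Reproducing the published corpus results

The headline frequencies this pipeline is designed to recompute — 72 of
111 meta-analyses significant (65%), 17 of 96 with a small-study effect
(18%), 53 of 95 with $O > E$ (56%), 19 excess-significance flags (20%),
and the 29-meta-analysis $\ge$10-study subsample (86%/31%/27%) — require
the per-study source records deposited at <https://osf.io/wpb69/>
(supplementary S4 table). Those records are not redistributable here;
once transcribed into the corpus CSV schema at
`inst/extdata/corpus_s4.csv`, the corresponding acceptance test runs the
full audit against them. The packaged ROBIS table, by contrast, is fully
in-package and its domain tallies (32 low in domain 1; 40, 28 and 30 high
in domains 2–4 of 49 reviews) are recomputed by `robis_tabulate()` in the
tests and the acceptance script.

## Limitations

Both bias statistics have low power at typical meta-analysis sizes, and
neither identifies the *source* of bias; heterogeneity can produce
spurious Egger signals through the correlation of log effects with their
variances. The Peters test, which avoids that artifact, needs 2×2 tables
that adjusted observational estimates rarely provide, and is out of scope
here, as are trim-and-fill, Copas-type selection models and p-curve. The
audit treats each meta-analysis as independent even though reviews of the
same exposure share primary studies.
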