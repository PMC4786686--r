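---
title: "Monitoring drug popularity and harm from search hit counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring drug popularity and harm from search hit counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popharm)
library(dplyr)
```

## The idea

Search-engine hit counts — the number of web pages an engine reports for a
query — are a cheap, instantly updatable proxy for how much attention a
psychoactive substance receives. popharm implements an infodemiology pipeline
built on two simple statistics computed from a panel of per-drug, per-date
hit counts:

* the **relative popularity index** of drug *i* at a date,
  \(P_i = N_i / \max_j(N_j) \times 100\%\), where \(N_i\) is the hit count of
  the exact-phrase query `"drug name"` — the most-searched drug scores 100 and
  everything else is expressed relative to it;
* the **harm index**,
  \(H_i = N_{i,\mathrm{harm}} / N_i \times 100\%\), where
  \(N_{i,\mathrm{harm}}\) is the hit count of the name conjoined with the
  disjunction `"harm" OR "harmful"` — the fraction of a drug's web presence
  that co-occurs with harm language.

Around these two ratios the package provides query construction and keyword
screening, panel loading and quality control, trend monitoring (rank
crossings, co-varying groups), validation of the harm index against an
external expert harm-score table, and a synthetic panel generator with known
ground truth.

Both indexes are invariant to rescaling all counts at a date by a common
positive factor, which matters because absolute hit counts are unstable
across time and engine versions; only the ratios are interpreted.

## Data model and quality control

A panel is a tidy table `drug, date, kind, count` with `kind` either `base`
or `harm` and one row per key. The `date` records the "results available
before this date" restriction of an advanced search; it is metadata, not a
claim about when pages were created.

Hit counts are engine-reported estimates, not set cardinalities. A
well-documented pathology is that a disjunctive query can return *fewer*
pages than either disjunct alone, so the logically impossible
`harm count > base count` does occur in real data. `qc_panel()` therefore
flags `harm_exceeds_base`, `zero_count`, and `missing_pair` (a harm record
with no base record) as warnings rather than refusing the data; the reporting
layer logs every anomaly and never drops records silently.

Keyword screening mirrors how a practitioner assembles the drug list:
multi-word names are excluded (exact-phrase counts for them are erratic), as
are names on an ambiguity blocklist — by default `tobacco` and `mushrooms`,
whose hits are dominated by the biological rather than the drug sense. Names
are lower-cased and trimmed before matching; the literature states the
exclusions but no normalization rule, so case-folding is this package's
choice.

## Numerical choices

* **Rounding.** Printed index tables use one decimal. We reproduce them with
  round-half-away-from-zero (`round_half_out()`), applied at presentation
  only (`rounding = "printed"`); every downstream computation uses full
  precision unless the caller explicitly asks for printed-grade values.
* **Ties in rankings** share a competition rank; display order within a tie
  is alphabetical, a deterministic stand-in for the unexplained ordering of
  equal printed values.
* **Drugs without a harm record are omitted** from the harm table with a
  message — absence of a query is not a zero count.
* **Degenerate inputs** (no base records at the date, an all-zero maximum, a
  harm record over a zero base) are errors naming the offending drug or date.

## Trends, crossings and co-variation

`build_series()` assembles one drug's (date, \(P_i\)) trajectory, either
computed from raw counts or transcribed from an already-indexed table (the
shipped six-date table stores printed indexes because the raw per-date counts
behind it were never published). `series_changes()` takes consecutive
differences.

"Changes in popularity correlate" is operationalized as the Pearson
correlation of first-difference series (`covariation()`, mode
`"differences"`; a `"levels"` mode is provided for sensitivity analysis —
no method is attached to the published pair lists). Constant series — notably the
reference drug pinned at 100 by construction — have undefined correlation and
are excluded and listed. Reported groups are maximal cliques of the graph
with an edge wherever \(r \ge\) threshold (enumerated with igraph); the
threshold default is 0.9 and is deliberately configurable because no
published cutoff exists, so the printed pair lists can only be compared
qualitatively.

A **rank crossing** between two drugs is an interval between consecutive
dates across which the sign of \(P_a - P_b\) changes. An exact tie carries no
sign; a crossing that passes through a tie is attributed to the interval that
ends it (the first date where the new ordering is strict), a deterministic
and testable rule. A dip to equality that reverts is not a crossing.

```{r}
tab2 <- paper_popularity_table()
detect_crossings(build_series(tab2, "cannabis"), build_series(tab2, "cocaine"))
```

## Validating the harm index

`validate_harm()` joins the harm table with an external expert harm-score
table (a 0–100 multicriteria rating produced by an independent scientific
panel; shipped as `harm_scores.csv`), computes the Pearson correlation over
complete pairs, and tests it with the standard two-sided t statistic
\(t = r\sqrt{(n-2)/(1-r^2)}\) on \(n-2\) degrees of freedom. No test is
stated alongside the published correlation; the t-test is the field standard for a
product-moment correlation and the implementation is guarded in the test
suite by a 100,000-draw permutation oracle (agreement within 10% relative
error at \(n = 10\)). Whether the published correlation was computed on
printed (one-decimal) or full-precision indexes is also unstated;
`use_printed_rounding` exposes both, and on the shipped 16-drug table both
modes round to the same published percentage (81.60% vs 81.59%), so the
choice is immaterial there. The "harm score ranking" phrasing is read as a
correlation of the score and index *values*; a rank-based correlation is a
different statistic (here 0.56) and is not what the published figure
reflects.

```{r}
v <- validate_harm(harm_index(paper_panel()), paper_harm_scores(),
                   use_printed_rounding = TRUE)
v
```

Note the t-based p-value (1.16e-4) is what this package computes and
defends by oracle; it is of the same order as, but not identical to, the
historically reported value for this table.

## The synthetic generator

Real hit-count panels cannot be re-downloaded reproducibly (engine counts
drift daily and scraping violates terms of service), so the data-provider
surface is deliberately limited to fixtures and simulation, and every
pipeline stage is exercised against panels with planted ground truth:

* **Base counts are log-normal** with per-drug `base_log_mean` (default
  \(\log 10^7\)) and `base_log_sd` (default 1.5): printed counts span four
  orders of magnitude, so a heavy-tailed positive model is the natural
  emulation. A per-drug `base_log_mean` lets a dominant reference drug be
  planted, mirroring the one substance that dwarfs the rest.
* **Trajectories are geometric random walks**: per step, log counts move by
  `log(trend_slopes)` plus `step_log_sd` (default 0.1) times a standard
  normal increment. `step_log_sd` is this package's addition — some scale for
  per-step variation is needed for trends to be stochastic at all — and
  setting it (with `base_log_sd` and `noise_sd`) to zero makes every series
  deterministic.
* **Planted co-variation**: within a declared group, step increments share a
  latent factor with loading \(\sqrt{\rho}\), giving pairwise correlation
  \(\rho\) exactly in population. Negative \(\rho\) is only attainable for
  two-member groups (loadings \(\pm\sqrt{|\rho|}\)).
* **Harm counts are binomial** draws from the base count at the planted
  per-drug proportion, which enforces the subset semantics the harm index
  assumes; optional multiplicative log-normal noise (`noise_sd`) can break
  that subset relation on purpose to exercise the QC checks.
* **Determinism**: all randomness flows from the single config seed through a
  local RNG stream; the caller's RNG state is untouched and the same config
  always yields byte-identical output.

What the generator does *not* emulate: engine-side estimation error, index
churn, personalization, or the OR-operator pathology (except through the
generic noise term). Passing recovery tests on synthetic panels therefore
shows the statistics are computed correctly, not that search counts are an
unbiased measure of drug use.

### Recovery properties and the sizes used

The test suite checks, at sizes chosen to keep the full suite under a minute
on one CPU:

* planted harm proportions are recovered by the harm index with mean absolute
  error well under 0.5 percentage points over 50 seeded replicates at base
  counts near \(5\times10^6\) (binomial concentration makes the expected
  error ~0.04 pp);
* a planted \(\rho = 0.95\) group of three drugs among eight (a stable
  dominant reference plus seven volatile drugs, 12 monthly dates) is
  recovered by `covariation()` at threshold 0.5 in at least 90% of 50 seeded
  replicates. *Recovered* means all planted members are reported together in
  one group. With only 11 difference observations, a threshold of 0.5 sits
  near the sampling quantile of chance correlations, so an unrelated drug
  occasionally joins the reported clique (it must correlate only with the
  group's one latent factor, not clear three independent hurdles); demanding
  the exact planted set and nothing more would measure that sampling
  artifact, not the detector.

## Known limitations

* Hit counts measure web presence, not consumption; co-variation of
  popularity is not evidence of co-use, and the harm index is a crude proxy
  that the validation exercise shows to track — not replace — expert harm
  assessment.
* The six-date trend table is transcribed at printed precision; differences
  of one-decimal values are coarse, which is another reason the co-variation
  threshold is left configurable rather than fixed.
* No live querying is implemented, by design: counts are non-reproducible
  and scraping violates engine terms of service. The loader accepts any CSV
  in the panel layout, so a user with their own (lawfully obtained) counts
  can run the identical analysis.
* No time-series modelling (seasonality, smoothing, ARIMA) is attempted; the
  method is deliberately a pair of ratios plus elementary correlation.
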