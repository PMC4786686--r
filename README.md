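# popharm

Infodemiology tools for monitoring the popularity of — and harm associated
with — psychoactive substances from search-engine hit counts.

Epidemiological surveillance of drug use is slow and expensive; the number of
web pages a search engine reports for a drug name is available instantly.
popharm turns panels of such hit counts into two interpretable statistics and
the analyses built on them, for researchers in digital epidemiology and
substance-use surveillance:

- **Relative popularity index**: for drug *i* at one date,
  *P*<sub>*i*</sub> = *N*<sub>*i*</sub> / max<sub>*j*</sub>(*N*<sub>*j*</sub>) × 100%,
  where *N*<sub>*i*</sub> is the hit count of the exact-phrase query
  `"drug name"`. The most-searched drug scores 100.
- **Harm index**:
  *H*<sub>*i*</sub> = *N*<sub>*i*,harm</sub> / *N*<sub>*i*</sub> × 100%,
  where *N*<sub>*i*,harm</sub> is the count for the name conjoined with
  `"harm" OR "harmful"` — the share of a drug's web presence that co-occurs
  with harm language.

On top of the indexes the package provides query construction and keyword
screening, panel loading and quality control (including the
harm-count-exceeds-base-count anomaly real engines produce), popularity
trajectories with rank-crossing detection, co-varying drug groups from
first-difference Pearson correlations, validation of the harm index against
an expert multicriteria harm-score table (Pearson *r* with a two-sided
*t*-test on *n* − 2 df), and a fully seeded synthetic panel generator with
planted trends, correlation groups and harm proportions. A transcription of a
published 16-drug panel (base and harm counts recorded 2014-06-20, a six-date
popularity table, and the expert harm scores) ships as plain-CSV fixtures.

## Worked example

```r
library(popharm)

panel <- paper_panel()                      # shipped 16-drug panel
head(popularity_index(panel, rounding = "printed"), 5)
#> # A tibble: 5 × 4
#>   date       drug         count index_percent
#>   <date>     <chr>        <dbl>         <dbl>
#> 1 2014-06-20 alcohol  389000000         100
#> 2 2014-06-20 cannabis  59100000          15.2
#> 3 2014-06-20 cocaine   58600000          15.1
#> 4 2014-06-20 lsd       48600000          12.5
#> 5 2014-06-20 heroin    46800000          12
```

Alcohol dominates the panel, so it defines the scale; cannabis draws 15.2% as
many hits. Validating the harm index against the expert harm scores:

```r
v <- validate_harm(harm_index(panel), paper_harm_scores(),
                   use_printed_rounding = TRUE)
glance(v)
#> # A tibble: 1 × 5
#>       n     r r_percent p_two_sided rounding
#>   <int> <dbl>     <dbl>       <dbl> <chr>
#> 1    16 0.816      81.6    0.000116 printed
```

A correlation of 81.6% across 16 drugs (p ≈ 1.2 × 10⁻⁴) means the crude
web-derived harm index tracks the expert panel's much more elaborate
assessment surprisingly well. `autoplot(v)` draws the score-vs-index scatter,
and `tidy(v)` returns the paired values.

Trend analysis on the six-date popularity table:

```r
tab2 <- paper_popularity_table()
detect_crossings(build_series(tab2, "cannabis"), build_series(tab2, "cocaine"))
#> # A tibble: 1 × 4
#>   drug_rising drug_falling date_before date_after
#>   <chr>       <chr>        <date>      <date>
#> 1 cannabis    cocaine      2014-02-01  2014-06-20
```

Cannabis overtook cocaine in relative popularity between February and June
2014. `covariation(tab2)` reports groups of drugs whose popularity *changes*
move together, and `run_full_analysis(run_config(...))` orchestrates every
stage and writes CSV/JSON reports plus a manifest. A thin command-line
wrapper lives at `inst/scripts/popharm.R` (subcommands `popularity`, `harm`,
`trends`, `validate`, `simulate`, `all`).

See the vignette (`vignettes/search-popularity-harm.Rmd`) for the model,
numerical choices and the synthetic generator's design.

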