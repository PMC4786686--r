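Package: popharm
Title: Popularity and Harm Indexes for Psychoactive Substances from
    Search-Engine Hit Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infodemiology pipeline for monitoring psychoactive-substance use
    from search-engine hit-count panels. Builds exact-phrase and harm-variant
    query strings, loads and quality-checks per-drug hit-count panels, computes
    relative popularity indexes (each drug's hit count as a percent of the
    maximum drug's count) and harm indexes (hit count of the name conjoined
    with "harm" OR "harmful" as a percent of the base count), tracks popularity
    trajectories over time, detects rank crossings and co-varying drug groups
    from first differences, and validates the harm index against an external
    expert harm-score table via Pearson correlation with a t-based significance
    test. Includes a seeded synthetic-panel generator with planted trends,
    correlation groups and harm proportions for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
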