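# Independent brute-force oracles, deliberately coded from first principles
# rather than through the package (or stats::cor) so that dual-route checks
# stay meaningful.

# One-line ratio definition of the popularity index.
ratio_oracle <- function(counts) {
  out <- numeric(length(counts))
  m <- counts[[1L]]
  for (c in counts) if (c > m) m <- c
  for (i in seq_along(counts)) out[[i]] <- counts[[i]] / m * 100
  out
}

# Textbook sum-of-products Pearson formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Two-sided permutation test for a correlation: proportion of label
# permutations whose |r| reaches the observed |r|.
perm_pvalue_oracle <- function(x, y, n_perm = 100000, seed = 1) {
  set.seed(seed)
  r_obs <- abs(pearson_oracle(x, y))
  hits <- 0L
  for (b in seq_len(n_perm)) {
    if (abs(pearson_oracle(x, sample(y))) >= r_obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Minimal panel builder for unit tests.
toy_panel <- function(drugs = c("alpha", "beta"),
                      base = c(1000, 500),
                      harm = NULL,
                      date = as.Date("2020-01-01")) {
  rows <- tibble::tibble(drug = drugs, date = date, kind = "base",
                         count = base)
  if (!is.null(harm)) {
    rows <- dplyr::bind_rows(
      rows,
      tibble::tibble(drug = drugs, date = date, kind = "harm", count = harm)
    )
  }
  rows
}

# Printed index columns of the shipped 16-drug tables, in the fixture's
# alphabetical drug order.
printed_popularity <- c(
  alcohol = 100, amphetamine = 2.3, benzodiazepines = 1.2,
  buprenorphine = 1.6, butane = 3.0, cannabis = 15.2, cocaine = 15.1,
  ecstasy = 11.0, ghb = 6.0, heroin = 12.0, ketamine = 2.2, khat = 2.7,
  lsd = 12.5, mephedrone = 0.5, methadone = 3.4, methamphetamine = 2.3
)
printed_harm <- c(
  alcohol = 27.5, amphetamine = 5.1, benzodiazepines = 10.3,
  buprenorphine = 5.8, butane = 3.3, cannabis = 4.6, cocaine = 25.6,
  ecstasy = 1.6, ghb = 1.2, heroin = 25.0, ketamine = 4.9, khat = 6.7,
  lsd = 1.2, mephedrone = 4.5, methadone = 4.1, methamphetamine = 5.8
)
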