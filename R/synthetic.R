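#' Configuration for the synthetic hit-count generator
#'
#' Describes a synthetic study: per-drug base hit counts are log-normal (real
#' hit counts span several orders of magnitude), each drug's series follows a
#' multiplicative trend with log-normal step noise, selected groups of drugs
#' share a latent step factor so their popularity *changes* are correlated at
#' a planted level, and harm-variant counts are binomial subsamples of the
#' base count at a planted per-drug proportion (optionally perturbed by
#' multiplicative log-normal noise, which can produce the kind of
#' set-logic-violating counts real engines return).
#'
#' @param n_drugs Number of drugs (default 8).
#' @param dates Strictly increasing vector of observation dates (default 12
#'   monthly dates starting 2013-01-01).
#' @param base_log_mean Mean of log initial base count; scalar or one value
#'   per drug (default `log(1e7)`). A per-drug value lets a dominant reference
#'   drug be planted, mirroring how one substance dwarfs the rest in real
#'   hit-count panels.
#' @param base_log_sd SD of log initial base count across drugs (default 1.5,
#'   spanning roughly two orders of magnitude).
#' @param trend_slopes Multiplicative growth per step; scalar or one value per
#'   drug (default 1, no trend).
#' @param groups List of planted co-variation groups, each a list with
#'   elements `drugs` (character vector of member names, or integer indexes)
#'   and `rho` (planted pairwise correlation of step log-increments; in
#'   \[0, 1\], or \[-1, 0) for two-member groups only).
#' @param harm_proportions Planted probability that a base hit also matches
#'   the harm query; scalar or per drug, each in \[0, 1\] (default 0.1).
#' @param step_log_sd SD of per-step log-increments; scalar or one value per
#'   drug (default 0.1). Zero makes a drug's trajectory exactly
#'   `slope^step`-deterministic.
#' @param noise_sd SD of multiplicative log-normal noise applied to harm
#'   counts (default 0, no noise).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config.
#' @param drug_names Optional drug names (default `drug01`, `drug02`, ...).
#' @return A `synthetic_config` list, validated.
#' @examples
#' cfg <- synthetic_config(n_drugs = 4, seed = 1)
#' @export
synthetic_config <- function(n_drugs = 8,
                             dates = seq(as.Date("2013-01-01"),
                                         by = "month", length.out = 12),
                             base_log_mean = log(1e7),
                             base_log_sd = 1.5,
                             trend_slopes = 1,
                             groups = list(),
                             harm_proportions = 0.1,
                             step_log_sd = 0.1,
                             noise_sd = 0,
                             seed = 1L,
                             drug_names = NULL) {
  problems <- character()
  if (!is.numeric(n_drugs) || length(n_drugs) != 1L || n_drugs < 1) {
    problems <- c(problems, "`n_drugs` must be a positive integer")
  } else {
    n_drugs <- as.integer(n_drugs)
  }
  dates <- as.Date(dates)
  if (anyNA(dates) || length(dates) < 1L || is.unsorted(dates, strictly = TRUE)) {
    problems <- c(problems, "`dates` must be strictly increasing dates")
  }
  if (is.null(drug_names)) {
    drug_names <- sprintf("drug%02d", seq_len(max(n_drugs, 1L)))
  } else {
    drug_names <- tolower(trimws(drug_names))
    if (length(drug_names) != n_drugs || anyDuplicated(drug_names)) {
      problems <- c(problems, "`drug_names` must be n_drugs unique names")
    }
  }
  recycle <- function(x, what) {
    if (length(x) == 1L) x <- rep(x, n_drugs)
    if (length(x) != n_drugs) {
      problems <<- c(problems, sprintf("`%s` must have length 1 or n_drugs", what))
    }
    x
  }
  trend_slopes <- recycle(trend_slopes, "trend_slopes")
  harm_proportions <- recycle(harm_proportions, "harm_proportions")
  base_log_mean <- recycle(base_log_mean, "base_log_mean")
  step_log_sd <- recycle(step_log_sd, "step_log_sd")
  if (any(trend_slopes <= 0)) {
    problems <- c(problems, "`trend_slopes` must be positive")
  }
  if (any(harm_proportions < 0 | harm_proportions > 1)) {
    problems <- c(problems, "`harm_proportions` must lie in [0, 1]")
  }
  if (any(step_log_sd < 0)) {
    problems <- c(problems, "`step_log_sd` must be >= 0")
  }
  for (nm in c("base_log_sd", "noise_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 0) {
      problems <- c(problems, sprintf("`%s` must be a single value >= 0", nm))
    }
  }
  groups <- purrr::map(groups, function(g) {
    if (!is.list(g) || is.null(g$drugs) || is.null(g$rho)) {
      problems <<- c(problems, "each group needs `drugs` and `rho`")
      return(g)
    }
    if (is.numeric(g$drugs)) g$drugs <- drug_names[g$drugs]
    g$drugs <- tolower(trimws(g$drugs))
    if (!all(g$drugs %in% drug_names) || length(g$drugs) < 2L) {
      problems <<- c(problems,
                     "group members must be >= 2 known drug names")
    }
    if (g$rho < -1 || g$rho > 1) {
      problems <<- c(problems, "group `rho` must lie in [-1, 1]")
    }
    if (g$rho < 0 && length(g$drugs) > 2L) {
      problems <<- c(problems,
                     "negative `rho` is only attainable for two-member groups")
    }
    g
  })
  all_members <- unlist(purrr::map(groups, "drugs"))
  if (anyDuplicated(all_members)) {
    problems <- c(problems, "groups must not share members")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    problems <- c(problems, "`seed` must be a single integer")
  }
  if (length(problems)) {
    abort(paste0("Invalid synthetic config:\n",
                 paste0("- ", problems, collapse = "\n")))
  }
  structure(
    list(
      n_drugs = n_drugs, dates = dates, drug_names = drug_names,
      base_log_mean = setNames(base_log_mean, drug_names),
      base_log_sd = base_log_sd,
      trend_slopes = setNames(trend_slopes, drug_names),
      groups = groups,
      harm_proportions = setNames(harm_proportions, drug_names),
      step_log_sd = setNames(step_log_sd, drug_names),
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# Run `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic hit-count panel with known ground truth
#'
#' Draws a panel according to a [synthetic_config()]: log base counts start
#' log-normal, evolve by `log(slope) + step_log_sd * increment` per step with
#' group-correlated increments (a shared latent factor with loading
#' `sqrt(rho)` yields pairwise correlation `rho` within a group), and harm
#' counts are binomial draws from the base count at the planted harm
#' proportion, optionally perturbed multiplicatively. The same config (and
#' seed) always produces an identical panel; the caller's RNG state is left
#' untouched.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `panel` (a validated hit-count panel tibble)
#'   and `truth` (the planted parameters: drug names, slopes, groups, harm
#'   proportions, seed).
#' @examples
#' sim <- generate_panel(synthetic_config(n_drugs = 4, seed = 42))
#' head(sim$panel)
#' @export
generate_panel <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    abort("`config` must come from synthetic_config().")
  }
  n <- config$n_drugs
  k <- length(config$dates)
  drugs <- config$drug_names

  sim <- with_local_seed(config$seed, {
    log_n <- matrix(NA_real_, nrow = n, ncol = k,
                    dimnames = list(drugs, NULL))
    log_n[, 1L] <- config$base_log_mean + config$base_log_sd * rnorm(n)
    if (k > 1L) {
      for (step in seq_len(k - 1L)) {
        eps <- rnorm(n)
        names(eps) <- drugs
        for (g in config$groups) {
          shared <- rnorm(1L)
          rho <- g$rho
          if (rho >= 0) {
            eps[g$drugs] <- sqrt(rho) * shared +
              sqrt(1 - rho) * rnorm(length(g$drugs))
          } else {
            load <- c(1, -1) * sqrt(abs(rho))
            eps[g$drugs] <- load * shared +
              sqrt(1 - abs(rho)) * rnorm(2L)
          }
        }
        log_n[, step + 1L] <- log_n[, step] +
          log(config$trend_slopes) + config$step_log_sd * eps[drugs]
      }
    }
    base <- round(exp(log_n))
    base[base < 1] <- 1

    harm <- matrix(NA_real_, nrow = n, ncol = k, dimnames = list(drugs, NULL))
    for (j in seq_len(n)) {
      p <- config$harm_proportions[[j]]
      for (t in seq_len(k)) {
        size <- base[j, t]
        harm[j, t] <- if (size <= .Machine$integer.max) {
          rbinom(1L, size = size, prob = p)
        } else {
          # counts beyond integer range: normal approximation to the binomial
          max(0, round(size * p + sqrt(size * p * (1 - p)) * rnorm(1L)))
        }
      }
    }
    if (config$noise_sd > 0) {
      harm <- round(harm * exp(config$noise_sd *
                                 matrix(rnorm(n * k), nrow = n)))
    }
    list(base = base, harm = harm)
  })

  panel <- dplyr::bind_rows(
    tidyr::expand_grid(drug = drugs, date = config$dates) |>
      dplyr::mutate(kind = "base",
                    count = as.vector(t(sim$base))),
    tidyr::expand_grid(drug = drugs, date = config$dates) |>
      dplyr::mutate(kind = "harm",
                    count = as.vector(t(sim$harm)))
  ) |>
    validate_panel()

  truth <- list(
    drug_names = drugs,
    dates = config$dates,
    trend_slopes = config$trend_slopes,
    groups = config$groups,
    harm_proportions = config$harm_proportions,
    noise_sd = config$noise_sd,
    seed = config$seed
  )
  list(panel = panel, truth = truth)
}

#' Write a generated panel and its ground truth to disk
#'
#' The panel goes to `<stem>.csv` (the standard panel layout) and the planted
#' parameters to `<stem>_truth.json`, so every generated dataset carries its
#' own answer key.
#'
#' @param sim A list from [generate_panel()].
#' @param stem Output path stem (without extension).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_synthetic <- function(sim, stem) {
  stopifnot(is.list(sim), !is.null(sim$panel), !is.null(sim$truth))
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, "_truth.json")
  write_panel(sim$panel, csv)
  truth <- sim$truth
  truth$dates <- format(truth$dates)
  truth$trend_slopes <- as.list(truth$trend_slopes)
  truth$harm_proportions <- as.list(truth$harm_proportions)
  jsonlite::write_json(truth, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv, json))
}

#' The published 16-drug hit-count panel
#'
#' Returns the transcribed panel behind the published tables: base hit counts
#' for 16 drugs (alcohol through mephedrone) and the matching harm-variant
#' counts, all recorded on 2014-06-20. This is real printed data shipped with
#' the package, used by the worked examples and the acceptance checks.
#'
#' @return A validated hit-count panel tibble (32 records: 16 base + 16 harm).
#' @examples
#' paper_panel()
#' @export
paper_panel <- function() {
  dplyr::bind_rows(
    read_panel(system.file("extdata", "table1_counts.csv", package = "popharm")),
    read_panel(system.file("extdata", "table3_harm.csv", package = "popharm"))
  ) |>
    validate_panel()
}

#' The external expert harm-score table
#'
#' Expert-panel multicriteria harm ratings (0-100 scale) for the 16 study
#' drugs, used as the external reference in [validate_harm()].
#'
#' @return A tibble with columns `drug` and `harm_score`.
#' @export
paper_harm_scores <- function() {
  read_harm_scores(system.file("extdata", "harm_scores.csv",
                               package = "popharm"))
}

#' The published popularity-index time table
#'
#' Printed relative popularity indexes for the 16 drugs at six observation
#' dates (May 2012 to June 2014). The raw per-date counts behind the earlier
#' dates were never published, so this table stores the printed indexes
#' themselves; the per-date maximum counts are available via
#' `paper_max_counts()`.
#'
#' @return A tibble with columns `drug`, `date`, `index_percent`.
#' @export
paper_popularity_table <- function() {
  read_index_table(system.file("extdata", "table2_popularity.csv",
                               package = "popharm"))
}

#' @rdname paper_popularity_table
#' @export
paper_max_counts <- function() {
  readr::read_csv(
    system.file("extdata", "table2_max_counts.csv", package = "popharm"),
    col_types = readr::cols(date = readr::col_date(),
                            max_count = readr::col_double())
  )
}
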