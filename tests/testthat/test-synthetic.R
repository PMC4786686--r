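test_that("config validation lists every offending field", {
  expect_error(
    synthetic_config(n_drugs = 3, harm_proportions = c(0.1, 1.5, -0.2),
                     trend_slopes = -1),
    "harm_proportions.*\\[0, 1\\]"
  )
  expect_error(synthetic_config(trend_slopes = 0), "positive")
  expect_error(
    synthetic_config(dates = as.Date(c("2020-02-01", "2020-01-01"))),
    "strictly increasing"
  )
  expect_error(
    synthetic_config(n_drugs = 4,
                     groups = list(list(drugs = c("drug01", "nosuch"),
                                        rho = 0.5))),
    "known drug names"
  )
  expect_error(
    synthetic_config(n_drugs = 4,
                     groups = list(list(drugs = paste0("drug0", 1:3),
                                        rho = -0.5))),
    "two-member"
  )
})

test_that("the same config always generates an identical panel and truth", {
  cfg <- synthetic_config(n_drugs = 6, seed = 17,
                          groups = list(list(drugs = c("drug01", "drug02"),
                                             rho = 0.8)))
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a, b)
  c <- generate_panel(synthetic_config(n_drugs = 6, seed = 18,
                                       groups = cfg$groups))
  expect_false(identical(a$panel, c$panel))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  first <- runif(1)
  set.seed(123)
  invisible(generate_panel(synthetic_config(n_drugs = 3, seed = 55)))
  expect_identical(runif(1), first)
})

test_that("no-signal configs yield constant popularity series", {
  cfg <- synthetic_config(n_drugs = 4, trend_slopes = 1, base_log_sd = 0,
                          step_log_sd = 0, noise_sd = 0, seed = 2)
  sim <- generate_panel(cfg)
  for (d in cfg$drug_names) {
    s <- build_series(sim$panel, d)
    expect_true(all(s$index_percent == s$index_percent[[1]]))
  }
})

test_that("noiseless large-count panels recover planted harm proportions", {
  # one replicate, tight bound from binomial concentration at n >= 1e6
  cfg <- synthetic_config(n_drugs = 4, dates = as.Date("2014-06-20"),
                          base_log_mean = log(5e6), base_log_sd = 0.1,
                          harm_proportions = 0.25, noise_sd = 0, seed = 9)
  h <- harm_index(generate_panel(cfg)$panel)
  expect_true(all(abs(h$harm_index_percent - 25) < 0.2))

  # mean absolute error over 50 seeded replicates with mixed proportions
  errs <- vapply(1:50, function(i) {
    cfg <- synthetic_config(
      n_drugs = 5, dates = as.Date("2014-06-20"),
      base_log_mean = log(5e6), base_log_sd = 0.2,
      harm_proportions = c(0.05, 0.1, 0.25, 0.3, 0.02),
      noise_sd = 0, seed = 2000 + i
    )
    sim <- generate_panel(cfg)
    h <- harm_index(sim$panel)
    truth <- sim$truth$harm_proportions[h$drug] * 100
    mean(abs(h$harm_index_percent - truth))
  }, numeric(1))
  expect_lt(mean(errs), 0.5)
})

test_that("planted slopes drive the popularity trajectory deterministically", {
  cfg <- synthetic_config(
    n_drugs = 3, base_log_mean = c(log(1e8), log(1e6), log(1e6)),
    base_log_sd = 0, step_log_sd = 0, trend_slopes = c(1, 1.2, 0.8),
    dates = seq(as.Date("2020-01-01"), by = "month", length.out = 6),
    seed = 4
  )
  sim <- generate_panel(cfg)
  up <- build_series(sim$panel, "drug02")$index_percent
  down <- build_series(sim$panel, "drug03")$index_percent
  expect_true(all(diff(up) > 0))
  expect_true(all(diff(down) < 0))
  # growth factor of the raw count matches the planted slope
  counts <- dplyr::filter(sim$panel, drug == "drug02", kind == "base")$count
  expect_equal(counts[2] / counts[1], 1.2, tolerance = 1e-3)
})

test_that("a planted high-correlation group is recovered from popularity changes", {
  group <- c("drug02", "drug03", "drug04")
  recovered <- vapply(1:50, function(i) {
    cfg <- synthetic_config(
      n_drugs = 8,
      base_log_mean = c(log(1e9), rep(log(1e6), 7)),
      base_log_sd = 0.3,
      step_log_sd = c(0, rep(0.15, 7)),
      groups = list(list(drugs = group, rho = 0.95)),
      seed = 1000 + i
    )
    sim <- generate_panel(cfg)
    idx <- purrr::map(sort(unique(sim$panel$date)),
                      \(d) popularity_index(sim$panel, d)) |>
      purrr::list_rbind() |>
      dplyr::select(drug, date, index_percent)
    cv <- covariation(idx, threshold = 0.5)
    # recovered as one group: all planted members reported together
    any(vapply(cv$groups, \(g) all(group %in% g), logical(1)))
  }, logical(1))
  expect_gte(mean(recovered), 0.9)
})

test_that("generated panels serialize with their ground truth", {
  sim <- generate_panel(synthetic_config(n_drugs = 3, seed = 12))
  stem <- file.path(withr::local_tempdir(), "sim")
  paths <- write_synthetic(sim, stem)
  expect_true(all(file.exists(paste0(stem, c(".csv", "_truth.json")))))
  expect_equal(read_panel(paste0(stem, ".csv")), sim$panel,
               ignore_attr = TRUE)
  truth <- jsonlite::read_json(paste0(stem, "_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 12)
  expect_equal(unlist(truth$harm_proportions),
               sim$truth$harm_proportions, tolerance = 1e-12)
})

test_that("the transcribed study panel is complete and clean", {
  panel <- paper_panel()
  expect_identical(nrow(panel), 32L)
  expect_identical(length(unique(panel$drug)), 16L)
  expect_identical(panel$count[panel$drug == "heroin" & panel$kind == "base"],
                   46800000)
  expect_identical(panel$count[panel$drug == "mephedrone" &
                                 panel$kind == "harm"], 92000)
  expect_identical(nrow(qc_panel(panel)), 0L)
})
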