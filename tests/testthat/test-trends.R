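tab2 <- paper_popularity_table()

test_that("series assembly reads transcribed index tables and raw panels", {
  cannabis <- build_series(tab2, "cannabis")
  expect_identical(attr(cannabis, "source"), "transcribed_index")
  expect_equal(cannabis$index_percent, c(6.3, 5.9, 6.9, 7.7, 10.1, 15.2))
  expect_false(is.unsorted(cannabis$date, strictly = TRUE))

  alcohol <- build_series(tab2, "alcohol")
  expect_true(all(alcohol$index_percent == 100))

  expect_error(build_series(tab2, "caffeine"), "not present")

  sim <- generate_panel(synthetic_config(n_drugs = 3, seed = 5))
  s <- build_series(sim$panel, "drug01")
  expect_identical(attr(s, "source"), "computed_from_counts")
  expect_identical(nrow(s), 12L)
})

test_that("consecutive changes reproduce hand-subtracted differences", {
  cannabis <- build_series(tab2, "cannabis")
  expect_equal(series_changes(cannabis)$change,
               c(-0.4, 1.0, 0.8, 2.4, 5.1))

  const <- build_series(tab2, "alcohol")
  expect_true(all(series_changes(const)$change == 0))

  two <- tibble::tibble(drug = "x",
                        date = as.Date(c("2020-01-01", "2020-02-01")),
                        index_percent = c(1.0, 3.5))
  expect_equal(series_changes(two)$change, 2.5)
  expect_error(series_changes(two[1, ]), "two points")
})

test_that("pairwise co-variation matches a hand-coded correlation oracle", {
  cv <- covariation(tab2, threshold = 0.9)
  expect_identical(cv$excluded, "alcohol")

  dc_cannabis <- diff(build_series(tab2, "cannabis")$index_percent)
  dc_cocaine <- diff(build_series(tab2, "cocaine")$index_percent)
  r_oracle <- pearson_oracle(dc_cannabis, dc_cocaine)
  expect_equal(cv$matrix["cannabis", "cocaine"], r_oracle, tolerance = 1e-12)

  expect_equal(cv$matrix, t(cv$matrix))
  expect_true(all(diag(cv$matrix) == 1))
  expect_true(all(vapply(cv$groups, length, integer(1)) >= 2))
})

test_that("identical, negated, and affinely rescaled series correlate as expected", {
  dates <- seq(as.Date("2020-01-01"), by = "month", length.out = 6)
  s <- c(1, 3, 2, 5, 4, 8)
  base <- tibble::tibble(drug = "a", date = dates, index_percent = s)
  twin <- tibble::tibble(drug = "b", date = dates, index_percent = s)
  neg <- tibble::tibble(drug = "c", date = dates, index_percent = -s)
  affine <- tibble::tibble(drug = "d", date = dates,
                           index_percent = 3.7 * s + 11)
  cv <- covariation(dplyr::bind_rows(base, twin, neg, affine), threshold = 0.99)
  expect_equal(cv$matrix["a", "b"], 1)
  expect_equal(cv$matrix["a", "c"], -1)
  expect_equal(cv$matrix["a", "d"], 1)
  expect_true(any(vapply(cv$groups, \(g) setequal(g, c("a", "b", "d")),
                         logical(1))))
})

test_that("co-variation rejects mismatched date grids and too-short series", {
  dates <- seq(as.Date("2020-01-01"), by = "month", length.out = 4)
  a <- tibble::tibble(drug = "a", date = dates, index_percent = 1:4)
  b <- tibble::tibble(drug = "b", date = dates[-2], index_percent = c(1, 5, 2))
  expect_error(covariation(dplyr::bind_rows(a, b)), "identical date grid")
  short <- dplyr::bind_rows(a[1:2, ], tibble::tibble(
    drug = "b", date = dates[1:2], index_percent = c(2, 1)
  ))
  expect_error(covariation(short), "three dates")
})

test_that("rank crossings fire on order reversals, mirror on swap, and skip stable pairs", {
  cannabis <- build_series(tab2, "cannabis")
  cocaine <- build_series(tab2, "cocaine")
  cr <- detect_crossings(cannabis, cocaine)
  expect_identical(nrow(cr), 1L)
  expect_identical(cr$drug_rising, "cannabis")
  expect_identical(cr$drug_falling, "cocaine")
  expect_identical(cr$date_before, as.Date("2014-02-01"))
  expect_identical(cr$date_after, as.Date("2014-06-20"))

  mirrored <- detect_crossings(cocaine, cannabis)
  expect_identical(mirrored$drug_rising, cr$drug_rising)
  expect_identical(mirrored$drug_falling, cr$drug_falling)

  lsd <- build_series(tab2, "lsd")
  heroin <- build_series(tab2, "heroin")
  cr2 <- detect_crossings(lsd, heroin)
  expect_identical(cr2$drug_rising, "lsd")
  expect_identical(cr2$drug_falling, "heroin")

  # cocaine stays at or above heroin on every date (one exact tie en route)
  expect_identical(nrow(detect_crossings(cocaine, heroin)), 0L)
  expect_identical(
    nrow(detect_crossings(build_series(tab2, "alcohol"), cannabis)), 0L
  )
})

test_that("exact ties attach the crossing to the following interval", {
  dates <- seq(as.Date("2020-01-01"), by = "month", length.out = 4)
  a <- tibble::tibble(drug = "a", date = dates,
                      index_percent = c(1, 5, 5, 9))
  b <- tibble::tibble(drug = "b", date = dates,
                      index_percent = c(2, 5, 5, 3))
  cr <- detect_crossings(a, b)
  expect_identical(nrow(cr), 1L)
  expect_identical(cr$date_before, dates[[3]])
  expect_identical(cr$date_after, dates[[4]])

  # a dips to a tie but never below: no reversal
  c1 <- tibble::tibble(drug = "a", date = dates,
                       index_percent = c(5, 4, 5, 6))
  c2 <- tibble::tibble(drug = "b", date = dates,
                       index_percent = c(3, 4, 3, 3))
  expect_identical(nrow(detect_crossings(c1, c2)), 0L)

  const_a <- tibble::tibble(drug = "a", date = dates, index_percent = 2)
  const_b <- tibble::tibble(drug = "b", date = dates, index_percent = 7)
  expect_identical(nrow(detect_crossings(const_a, const_b)), 0L)
})

test_that("trend plots are well-formed ggplot objects", {
  p <- plot_trends(tab2, drugs = c("cannabis", "cocaine"))
  expect_s3_class(p, "ggplot")
})
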