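#' Popularity trajectory of one drug
#'
#' Assembles the ordered (date, popularity index) series for a drug, either by
#' computing the index from a raw hit-count panel at every date (source
#' `"computed_from_counts"`) or by reading an already-indexed table with
#' columns `drug`, `date`, `index_percent` (source `"transcribed_index"`).
#'
#' @param x A hit-count panel (columns `drug`, `date`, `kind`, `count`) or an
#'   index table (columns `drug`, `date`, `index_percent`).
#' @param drug Drug name.
#' @return A tibble with columns `drug`, `date`, `index_percent`, sorted by
#'   date, with a `source` attribute.
#' @examples
#' tab2 <- read_index_table(
#'   system.file("extdata", "table2_popularity.csv", package = "popharm")
#' )
#' build_series(tab2, "cannabis")
#' @export
build_series <- function(x, drug) {
  stopifnot(is.data.frame(x), is.character(drug), length(drug) == 1L)
  drug <- tolower(trimws(drug))
  if (all(c("kind", "count") %in% names(x))) {
    panel <- validate_panel(x)
    source <- "computed_from_counts"
    series <- purrr::map(sort(unique(panel$date)), function(d) {
      popularity_index(panel, d)
    }) |>
      purrr::list_rbind() |>
      dplyr::filter(.data$drug == !!drug) |>
      dplyr::select("drug", "date", "index_percent")
  } else if ("index_percent" %in% names(x)) {
    source <- "transcribed_index"
    series <- tibble::as_tibble(x) |>
      dplyr::mutate(drug = tolower(trimws(.data$drug)),
                    date = as.Date(.data$date)) |>
      dplyr::filter(.data$drug == !!drug) |>
      dplyr::select("drug", "date", "index_percent")
  } else {
    abort("`x` must be a hit-count panel or an index table with `index_percent`.")
  }
  if (nrow(series) == 0L) {
    abort(sprintf("Drug '%s' is not present in the input.", drug))
  }
  series <- dplyr::arrange(series, .data$date)
  if (anyDuplicated(series$date)) {
    abort(sprintf("Drug '%s' has duplicate dates in the input.", drug))
  }
  attr(series, "source") <- source
  series
}

#' Read an index table (drug, date, index_percent) from CSV
#'
#' @param path Path to a CSV with header `drug,date,index_percent`.
#' @return A tibble with parsed dates and lower-cased drug names.
#' @export
read_index_table <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      drug = readr::col_character(),
      date = readr::col_date(),
      index_percent = readr::col_double()
    )
  ) |>
    dplyr::mutate(drug = tolower(trimws(.data$drug)))
}

#' First differences of a popularity series
#'
#' Element k is the index at date k+1 minus the index at date k; the changes
#' in popularity between consecutive observation dates.
#'
#' @param series A series from [build_series()] (or any tibble with `date` and
#'   `index_percent`), with at least two points.
#' @return A tibble with columns `from`, `to` (the interval endpoints) and
#'   `change` (percentage-point difference); one row fewer than the series.
#' @export
series_changes <- function(series) {
  stopifnot(is.data.frame(series),
            all(c("date", "index_percent") %in% names(series)))
  series <- dplyr::arrange(tibble::as_tibble(series), .data$date)
  n <- nrow(series)
  if (n < 2L) {
    abort("At least two points are required to compute changes.")
  }
  tibble::tibble(
    from = series$date[-n],
    to = series$date[-1L],
    change = diff(series$index_percent)
  )
}

#' Co-variation of popularity series across drugs
#'
#' Computes the Pearson correlation between every pair of drugs' popularity
#' trajectories — by default on the first differences of the series
#' (co-variation of *changes* in popularity), optionally on the raw levels —
#' and reports maximal groups of drugs whose pairwise correlations all reach a
#' threshold. Drugs with a constant series (for which the correlation is
#' undefined, notably the reference drug pinned at 100) are excluded and
#' listed, never silently dropped. Groups are maximal cliques of the graph
#' with an edge wherever r >= threshold; each group has at least two members.
#'
#' Co-variation of search popularity is all that is measured; it is at most a
#' hypothesis-generating signal about substances being used together.
#'
#' @param index_table A tibble with columns `drug`, `date`, `index_percent`
#'   covering two or more drugs on an identical date grid.
#' @param threshold Minimum pairwise correlation for group membership, in
#'   \[-1, 1\] (default 0.9).
#' @param mode `"differences"` (default) correlates first differences and
#'   needs at least three dates; `"levels"` correlates the raw series.
#' @return An object of class `covariation_result`: a list with `pairs`
#'   (tibble `drug_a`, `drug_b`, `r`), `matrix` (symmetric correlation
#'   matrix), `groups` (list of character vectors), `excluded` (constant-series
#'   drugs), `threshold`, and `mode`. `tidy()` returns the pair table.
#' @examples
#' tab2 <- read_index_table(
#'   system.file("extdata", "table2_popularity.csv", package = "popharm")
#' )
#' cv <- covariation(tab2, threshold = 0.9)
#' cv$groups
#' @export
covariation <- function(index_table, threshold = 0.9,
                        mode = c("differences", "levels")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(index_table),
            all(c("drug", "date", "index_percent") %in% names(index_table)),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= -1, threshold <= 1)
  tab <- tibble::as_tibble(index_table) |>
    dplyr::mutate(drug = tolower(trimws(.data$drug)),
                  date = as.Date(.data$date))
  wide <- tidyr::pivot_wider(tab, names_from = "drug",
                             values_from = "index_percent") |>
    dplyr::arrange(.data$date)
  mat <- as.matrix(wide[, setdiff(names(wide), "date"), drop = FALSE])
  if (anyNA(mat)) {
    abort("All drugs must share an identical date grid (no missing values).")
  }
  n_dates <- nrow(mat)
  if (mode == "differences") {
    if (n_dates < 3L) {
      abort("`differences` mode needs at least three dates.")
    }
    mat <- apply(mat, 2L, diff)
  } else if (n_dates < 2L) {
    abort("At least two dates are required.")
  }
  sds <- apply(mat, 2L, stats::sd)
  excluded <- colnames(mat)[sds == 0]
  keep <- colnames(mat)[sds > 0]
  if (length(keep) < 2L) {
    abort("Fewer than two non-constant series; no pairwise correlation to compute.")
  }
  cmat <- stats::cor(mat[, keep, drop = FALSE])

  pair_idx <- which(upper.tri(cmat), arr.ind = TRUE)
  pairs <- tibble::tibble(
    drug_a = rownames(cmat)[pair_idx[, 1L]],
    drug_b = colnames(cmat)[pair_idx[, 2L]],
    r = cmat[pair_idx]
  ) |>
    dplyr::arrange(dplyr::desc(.data$r))

  adj <- (cmat >= threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cliques <- igraph::max_cliques(g, min = 2L)
  groups <- purrr::map(cliques, \(cl) sort(igraph::V(g)$name[cl]))
  groups <- groups[order(purrr::map_int(groups, length),
                         purrr::map_chr(groups, 1L),
                         decreasing = c(TRUE, FALSE), method = "radix")]

  structure(
    list(pairs = pairs, matrix = cmat, groups = groups,
         excluded = excluded, threshold = threshold, mode = mode),
    class = "covariation_result"
  )
}

#' @export
print.covariation_result <- function(x, ...) {
  cat(sprintf(
    "Co-variation of popularity series (%s mode, threshold r >= %g)\n",
    x$mode, x$threshold
  ))
  cat(sprintf("%d drugs correlated; excluded as constant: %s\n",
              ncol(x$matrix),
              if (length(x$excluded)) paste(x$excluded, collapse = ", ")
              else "none"))
  if (length(x$groups)) {
    cat("Co-varying groups:\n")
    for (g in x$groups) cat("  -", paste(g, collapse = ", "), "\n")
  } else {
    cat("No co-varying groups at this threshold.\n")
  }
  invisible(x)
}

#' @rdname covariation
#' @param x A `covariation_result`.
#' @param ... Unused.
#' @method tidy covariation_result
#' @export
tidy.covariation_result <- function(x, ...) {
  x$pairs
}

#' Detect rank crossings between two drugs
#'
#' Finds the intervals between consecutive observation dates across which the
#' popularity ordering of two drugs reverses: the sign of the difference of
#' their indexes changes. An exact tie at a date carries no sign; the crossing
#' it participates in is attributed to the following interval. A pair whose
#' ordering is stable across all dates yields zero crossings.
#'
#' @param series_a,series_b Series from [build_series()] on an identical date
#'   grid with at least two dates.
#' @return A tibble with one row per crossing: `drug_rising`, `drug_falling`,
#'   `date_before`, `date_after`.
#' @examples
#' tab2 <- read_index_table(
#'   system.file("extdata", "table2_popularity.csv", package = "popharm")
#' )
#' detect_crossings(build_series(tab2, "cannabis"), build_series(tab2, "cocaine"))
#' @export
detect_crossings <- function(series_a, series_b) {
  for (s in list(series_a, series_b)) {
    stopifnot(is.data.frame(s),
              all(c("drug", "date", "index_percent") %in% names(s)))
  }
  a <- dplyr::arrange(tibble::as_tibble(series_a), .data$date)
  b <- dplyr::arrange(tibble::as_tibble(series_b), .data$date)
  if (nrow(a) != nrow(b) || !all(a$date == b$date)) {
    abort("The two series must share an identical date grid.")
  }
  if (nrow(a) < 2L) {
    abort("At least two dates are required to detect crossings.")
  }
  drug_a <- a$drug[[1L]]
  drug_b <- b$drug[[1L]]
  d <- sign(a$index_percent - b$index_percent)

  out <- tibble::tibble(
    drug_rising = character(), drug_falling = character(),
    date_before = as.Date(character()), date_after = as.Date(character())
  )
  last_sign <- 0
  for (k in seq_along(d)) {
    s <- d[[k]]
    if (s == 0) next
    if (last_sign != 0 && s != last_sign) {
      rising <- if (s > 0) drug_a else drug_b
      falling <- if (s > 0) drug_b else drug_a
      out <- dplyr::bind_rows(out, tibble::tibble(
        drug_rising = rising, drug_falling = falling,
        date_before = a$date[[k - 1L]], date_after = a$date[[k]]
      ))
    }
    last_sign <- s
  }
  out
}

#' Plot popularity trajectories
#'
#' Line plot of the popularity index over time for the drugs in an index
#' table, on a log scale by default since the index spans orders of magnitude.
#'
#' @param index_table A tibble with columns `drug`, `date`, `index_percent`.
#' @param drugs Optional subset of drugs to plot.
#' @param log_scale Use a log10 y axis (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_trends <- function(index_table, drugs = NULL, log_scale = TRUE) {
  tab <- tibble::as_tibble(index_table) |>
    dplyr::mutate(drug = tolower(trimws(.data$drug)),
                  date = as.Date(.data$date))
  if (!is.null(drugs)) {
    tab <- dplyr::filter(tab, .data$drug %in% tolower(trimws(drugs)))
  }
  p <- ggplot2::ggplot(
    tab,
    ggplot2::aes(x = .data$date, y = .data$index_percent,
                 colour = .data$drug)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "Relative popularity index (%)",
                  colour = "Drug") +
    ggplot2::theme_minimal()
  if (log_scale) p <- p + ggplot2::scale_y_log10()
  p
}
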