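#' Pearson product-moment correlation
#'
#' Standard product-moment correlation at full precision, with explicit
#' guards: both vectors must have equal length of at least 3 and neither may
#' be constant (the correlation is undefined for a zero-variance vector).
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return The correlation coefficient in \[-1, 1\].
#' @examples
#' pearson_r(1:5, c(2, 4, 6, 8, 10))
#' @export
pearson_r <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.")
  }
  if (length(x) < 3L) {
    abort("At least three paired observations are required.")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("Missing values are not allowed.")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation is undefined for a constant vector.")
  }
  stats::cor(x, y)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Tests the null hypothesis of zero correlation with the standard
#' t-statistic \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of
#' freedom. For |r| = 1 the statistic is unbounded and the p-value is 0.
#'
#' @param r Correlation coefficient in \[-1, 1\].
#' @param n Number of paired observations (>= 3).
#' @return Two-sided p-value in \[0, 1\].
#' @examples
#' correlation_pvalue(0.816, 16)
#' @export
correlation_pvalue <- function(r, n) {
  stopifnot(is.numeric(r), length(r) == 1L, is.numeric(n), length(n) == 1L)
  if (is.na(r) || abs(r) > 1) {
    abort("`r` must lie in [-1, 1].")
  }
  if (n < 3) {
    abort("`n` must be at least 3.")
  }
  if (abs(r) == 1) {
    return(0)
  }
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Read an external harm-score table from CSV
#'
#' @param path Path to a CSV with header `drug,harm_score` (expert-panel
#'   multicriteria harm ratings on a 0-100 scale).
#' @return A tibble with lower-cased drug names.
#' @examples
#' read_harm_scores(system.file("extdata", "harm_scores.csv", package = "popharm"))
#' @export
read_harm_scores <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      drug = readr::col_character(),
      harm_score = readr::col_double()
    )
  ) |>
    dplyr::mutate(drug = tolower(trimws(.data$drug)))
}

#' Validate the harm index against external expert harm scores
#'
#' Quantifies the agreement between the search-derived harm index and an
#' expert-panel harm score by the Pearson correlation over the drugs present
#' in both tables, with a two-sided t-test p-value ([correlation_pvalue()]).
#' With `use_printed_rounding = TRUE` the harm indexes are first rounded to
#' one decimal (the precision at which index tables are printed) so the
#' correlation is computed on presentation-grade values; otherwise full
#' precision is used.
#'
#' @param harm_table Output of [harm_index()] (columns `drug` and
#'   `harm_index_percent`), or any tibble with those columns.
#' @param harm_scores A tibble with columns `drug` and `harm_score` (see
#'   [read_harm_scores()]). May be omitted if `harm_table` already carries a
#'   `harm_score` column.
#' @param use_printed_rounding Round harm indexes to one decimal before
#'   correlating (default `FALSE`).
#' @return An object of class `harm_validation`: a list with `n`, `r`,
#'   `r_percent`, `p_two_sided`, `rounding` and `pairs_used` (tibble `drug`,
#'   `harm_index`, `harm_score`). `tidy()` returns the pair table, `glance()`
#'   the one-row summary, and `autoplot()` the score-vs-index scatter.
#' @examples
#' scores <- read_harm_scores(
#'   system.file("extdata", "harm_scores.csv", package = "popharm")
#' )
#' validate_harm(harm_index(paper_panel()), scores)
#' @export
validate_harm <- function(harm_table, harm_scores = NULL,
                          use_printed_rounding = FALSE) {
  stopifnot(is.data.frame(harm_table),
            all(c("drug", "harm_index_percent") %in% names(harm_table)))
  tab <- tibble::as_tibble(harm_table) |>
    dplyr::mutate(drug = tolower(trimws(.data$drug)))
  if (!is.null(harm_scores)) {
    stopifnot(is.data.frame(harm_scores),
              all(c("drug", "harm_score") %in% names(harm_scores)))
    scores <- tibble::as_tibble(harm_scores) |>
      dplyr::mutate(drug = tolower(trimws(.data$drug))) |>
      dplyr::select("drug", "harm_score")
    tab <- dplyr::left_join(dplyr::select(tab, -dplyr::any_of("harm_score")),
                            scores, by = "drug")
  } else if (!"harm_score" %in% names(tab)) {
    abort("Provide `harm_scores`, or a `harm_score` column in `harm_table`.")
  }
  pairs <- tab |>
    dplyr::filter(!is.na(.data$harm_index_percent), !is.na(.data$harm_score)) |>
    dplyr::transmute(
      drug = .data$drug,
      harm_index = if (use_printed_rounding) {
        round_half_out(.data$harm_index_percent, 1)
      } else {
        .data$harm_index_percent
      },
      harm_score = .data$harm_score
    ) |>
    dplyr::arrange(.data$drug)
  if (nrow(pairs) < 3L) {
    abort(sprintf(
      "Only %d drug(s) have both a harm index and a harm score; at least 3 are required.",
      nrow(pairs)
    ))
  }
  r <- pearson_r(pairs$harm_index, pairs$harm_score)
  structure(
    list(
      n = nrow(pairs),
      r = r,
      r_percent = r * 100,
      p_two_sided = correlation_pvalue(r, nrow(pairs)),
      rounding = if (use_printed_rounding) "printed" else "full",
      pairs_used = pairs
    ),
    class = "harm_validation"
  )
}

#' @export
print.harm_validation <- function(x, ...) {
  cat("Harm index vs expert harm score\n")
  cat(sprintf("  n = %d paired drugs (%s-precision indexes)\n",
              x$n, x$rounding))
  cat(sprintf("  Pearson r = %.3f (%.1f%%), two-sided p = %.3g\n",
              x$r, x$r_percent, x$p_two_sided))
  invisible(x)
}

#' @rdname validate_harm
#' @param x A `harm_validation` object.
#' @param ... Unused.
#' @method tidy harm_validation
#' @export
tidy.harm_validation <- function(x, ...) {
  x$pairs_used
}

#' @rdname validate_harm
#' @method glance harm_validation
#' @export
glance.harm_validation <- function(x, ...) {
  tibble::tibble(
    n = x$n, r = x$r, r_percent = x$r_percent,
    p_two_sided = x$p_two_sided, rounding = x$rounding
  )
}

#' @rdname validate_harm
#' @param object A `harm_validation` object.
#' @method autoplot harm_validation
#' @export
autoplot.harm_validation <- function(object, ...) {
  ggplot2::ggplot(
    object$pairs_used,
    ggplot2::aes(x = .data$harm_score, y = .data$harm_index)
  ) +
    ggplot2::geom_point(shape = 15, colour = "steelblue", size = 2) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linewidth = 0.4) +
    ggplot2::labs(
      x = "Expert harm score (0-100)",
      y = "Harm index (%)",
      title = sprintf("Pearson r = %.1f%%, p = %.3g (n = %d)",
                      object$r_percent, object$p_two_sided, object$n)
    ) +
    ggplot2::theme_minimal()
}
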