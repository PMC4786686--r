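#' Round half away from zero
#'
#' Presentation rounding used for printed index values: ties are rounded away
#' from zero (4.05 -> 4.1), unlike base R's round-half-to-even. All internal
#' computation stays at full precision; this rounding is applied only when a
#' printed-style value is requested.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the printed precision of
#'   the index tables).
#' @return Rounded numeric vector.
#' @examples
#' round_half_out(c(4.05, -4.05, 15.19), 1)
#' @export
round_half_out <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Relative popularity index at one date
#'
#' For every drug with a base hit count at the chosen date, computes the
#' relative popularity index: the drug's hit count as a percentage of the
#' maximum drug's hit count at that date,
#' \deqn{P_i = \frac{N_i}{\max_j(N_j)} \times 100\%.}
#' The most-searched drug therefore scores exactly 100 and every other drug a
#' value in (0, 100]. Scaling all counts at the date by a common positive
#' factor leaves every index unchanged.
#'
#' @param panel A hit-count panel accepted by [validate_panel()].
#' @param date Date (or ISO-8601 string) to index; defaults to the only date
#'   present when the panel has exactly one.
#' @param rounding `"full"` (default) keeps full precision; `"printed"`
#'   rounds `index_percent` to one decimal, half away from zero.
#'
#' @return A tibble with columns `date`, `drug`, `count`, and `index_percent`,
#'   sorted by descending count (ties alphabetical). The drug attaining the
#'   maximum is recorded in the `max_drug` attribute.
#' @examples
#' popularity_index(paper_panel(), rounding = "printed")
#' @export
popularity_index <- function(panel, date = NULL,
                             rounding = c("full", "printed")) {
  rounding <- match.arg(rounding)
  panel <- validate_panel(panel)
  date <- resolve_panel_date(panel, date)
  base <- dplyr::filter(panel, .data$kind == "base", .data$date == !!date)
  if (nrow(base) == 0L) {
    abort(sprintf("No base hit-count records at date %s.", format(date)))
  }
  max_count <- max(base$count)
  if (max_count == 0) {
    abort(sprintf(
      "All base counts at date %s are zero; the popularity index is undefined.",
      format(date)
    ))
  }
  out <- base |>
    dplyr::transmute(
      date = .data$date,
      drug = .data$drug,
      count = .data$count,
      index_percent = .data$count / max_count * 100
    ) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$drug)
  if (rounding == "printed") {
    out$index_percent <- round_half_out(out$index_percent, 1)
  }
  attr(out, "max_drug") <- out$drug[which.max(out$count)]
  attr(out, "rounding") <- rounding
  out
}

#' Harm index at one date
#'
#' For every drug with both a harm-variant and a base hit count at the chosen
#' date, computes the harm index: the hit count of the drug name conjoined
#' with "harm" OR "harmful" as a percentage of the drug's base hit count,
#' \deqn{H_i = \frac{N_{i,\mathrm{harm}}}{N_i} \times 100\%.}
#' Drugs with a base record but no harm record are omitted with a message
#' (absence of the harm query is not a zero count). A harm record whose base
#' count is zero is an error, since the ratio is undefined.
#'
#' @inheritParams popularity_index
#' @return A tibble with columns `date`, `drug`, `base_count`, `harm_count`,
#'   and `harm_index_percent`, sorted by descending harm index (ties
#'   alphabetical).
#' @examples
#' harm_index(paper_panel(), rounding = "printed")
#' @export
harm_index <- function(panel, date = NULL, rounding = c("full", "printed")) {
  rounding <- match.arg(rounding)
  panel <- validate_panel(panel)
  date <- resolve_panel_date(panel, date)
  at_date <- dplyr::filter(panel, .data$date == !!date)
  wide <- tidyr::pivot_wider(at_date, names_from = "kind",
                             values_from = "count")
  if (!"harm" %in% names(wide)) wide$harm <- NA_real_
  if (!"base" %in% names(wide)) wide$base <- NA_real_

  orphan <- dplyr::filter(wide, !is.na(.data$harm), is.na(.data$base))
  if (nrow(orphan)) {
    abort(sprintf(
      "Harm record without a base record at %s for: %s.",
      format(date), paste(orphan$drug, collapse = ", ")
    ))
  }
  zero_base <- dplyr::filter(wide, !is.na(.data$harm), .data$base == 0)
  if (nrow(zero_base)) {
    abort(sprintf(
      "Base count is zero at %s for: %s; the harm index is undefined.",
      format(date), paste(zero_base$drug, collapse = ", ")
    ))
  }
  skipped <- dplyr::filter(wide, is.na(.data$harm), !is.na(.data$base))
  if (nrow(skipped)) {
    inform(sprintf(
      "Omitting %d drug(s) without a harm-variant record at %s: %s.",
      nrow(skipped), format(date), paste(skipped$drug, collapse = ", ")
    ))
  }
  out <- wide |>
    dplyr::filter(!is.na(.data$harm)) |>
    dplyr::transmute(
      date = .data$date,
      drug = .data$drug,
      base_count = .data$base,
      harm_count = .data$harm,
      harm_index_percent = .data$harm / .data$base * 100
    ) |>
    dplyr::arrange(dplyr::desc(.data$harm_index_percent), .data$drug)
  if (rounding == "printed") {
    out$harm_index_percent <- round_half_out(out$harm_index_percent, 1)
  }
  attr(out, "rounding") <- rounding
  out
}

#' Rank drugs by an index value
#'
#' Sorts descending by value and assigns competition ("min") ranks: exact ties
#' share a rank and the next rank skips accordingly. Display order within a
#' tie is alphabetical by drug name.
#'
#' @param values A data frame with a `drug` column and one value column (by
#'   default the first non-`drug` numeric column; name it explicitly with
#'   `value_col`).
#' @param criterion Label recorded on the result, `"popularity"` or `"harm"`.
#' @param value_col Optional name of the value column.
#' @return A tibble with columns `rank`, `drug`, `value`, and `criterion`.
#' @examples
#' paper_panel() |> harm_index() |> rank_table("harm")
#' @export
rank_table <- function(values, criterion = c("popularity", "harm"),
                       value_col = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(is.data.frame(values))
  if (nrow(values) == 0L) {
    return(tibble::tibble(rank = integer(), drug = character(),
                          value = numeric(), criterion = character()))
  }
  if (is.null(value_col)) {
    candidates <- setdiff(names(values)[vapply(values, is.numeric, logical(1))],
                          "drug")
    preferred <- intersect(c("index_percent", "harm_index_percent"), candidates)
    value_col <- if (length(preferred)) preferred[[1L]] else candidates[[1L]]
  }
  out <- tibble::tibble(
    drug = values$drug,
    value = values[[value_col]]
  ) |>
    dplyr::arrange(dplyr::desc(.data$value), .data$drug) |>
    dplyr::mutate(
      rank = dplyr::min_rank(dplyr::desc(.data$value)),
      criterion = criterion
    ) |>
    dplyr::select("rank", "drug", "value", "criterion")
  out
}

# Resolve the target date of an index computation: explicit argument, or the
# panel's single date.
resolve_panel_date <- function(panel, date) {
  if (!is.null(date)) {
    return(as.Date(date))
  }
  dates <- unique(panel$date)
  if (length(dates) == 0L) {
    abort("No base hit-count records: the panel is empty.")
  }
  if (length(dates) != 1L) {
    abort(paste0(
      "`date` must be given when the panel covers ",
      length(dates), " dates."
    ))
  }
  dates
}
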