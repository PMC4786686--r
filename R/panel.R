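#' Validate a hit-count panel
#'
#' A hit-count panel is a tidy table of search-engine hit counts with one row
#' per `(drug, date, kind)` combination: `kind = "base"` rows hold the hit
#' count of the bare drug-name query and `kind = "harm"` rows the count of the
#' name conjoined with the harm-term disjunction. `validate_panel()` checks the
#' column contract and key uniqueness and returns the panel with normalized
#' column types, ordered by drug then date then kind.
#'
#' @param panel A data frame with columns `drug` (character), `date` (Date or
#'   ISO-8601 string), `kind` (`"base"` or `"harm"`), and `count`
#'   (non-negative integer-valued).
#'
#' @return A tibble with columns `drug`, `date` (Date), `kind`, `count`
#'   (double, integer-valued).
#' @export
validate_panel <- function(panel) {
  if (!is.data.frame(panel)) {
    abort("`panel` must be a data frame.")
  }
  required <- c("drug", "date", "kind", "count")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols)) {
    abort(paste0(
      "`panel` is missing required column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  panel <- tibble::as_tibble(panel)[required]
  panel$drug <- tolower(trimws(as.character(panel$drug)))
  panel$date <- as.Date(panel$date)
  panel$kind <- as.character(panel$kind)
  panel$count <- as.numeric(panel$count)

  if (nrow(panel) == 0L) {
    return(panel)
  }
  if (anyNA(panel$date)) {
    abort("`date` contains values that cannot be parsed as ISO-8601 dates.")
  }
  bad_kind <- setdiff(unique(panel$kind), c("base", "harm"))
  if (length(bad_kind)) {
    abort(paste0(
      "Unknown query kind(s): ", paste(bad_kind, collapse = ", "),
      ". `kind` must be 'base' or 'harm'."
    ))
  }
  if (anyNA(panel$count) || any(panel$count < 0) ||
      any(panel$count != trunc(panel$count))) {
    abort("`count` must be a non-negative integer for every record.")
  }
  key <- paste(panel$drug, panel$date, panel$kind, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- panel[which(dup)[1L], ]
    abort(sprintf(
      "Duplicate panel key: drug '%s', date %s, kind '%s'.",
      first$drug, format(first$date), first$kind
    ))
  }
  dplyr::arrange(panel, .data$drug, .data$date, .data$kind)
}

#' Read a hit-count panel from a delimited file
#'
#' Reads a CSV with header `drug,date,kind,count` (dates ISO-8601, counts
#' plain integers without thousands separators) and validates it with
#' [validate_panel()]. An empty file with only a header yields an empty panel.
#'
#' @param path Path to the CSV file.
#' @return A validated panel tibble (see [validate_panel()]).
#' @examples
#' path <- system.file("extdata", "table1_counts.csv", package = "popharm")
#' read_panel(path)
#' @export
read_panel <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      drug = readr::col_character(),
      date = readr::col_date(),
      kind = readr::col_character(),
      count = readr::col_double()
    )
  )
  validate_panel(raw)
}

#' Write a hit-count panel to CSV
#'
#' Inverse of [read_panel()]: writes the `drug,date,kind,count` layout with
#' ISO-8601 dates and plain integer counts, so that reading the file back
#' reproduces the panel records exactly.
#'
#' @param panel A panel accepted by [validate_panel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  panel <- validate_panel(panel)
  out <- panel
  out$count <- sprintf("%.0f", out$count)
  readr::write_csv(out, path)
  invisible(path)
}

#' Quality-control checks on a hit-count panel
#'
#' Search-engine hit counts are estimates and can violate elementary set
#' logic (a disjunctive query can return fewer pages than either term alone),
#' so anomalies are reported as warnings rather than rejected. Three checks
#' are run per drug/date:
#'
#' * `harm_exceeds_base`: the harm-variant count exceeds the base count, even
#'   though the harm query is logically a subset of the base query.
#' * `zero_count`: a recorded count of zero hits.
#' * `missing_pair`: a harm record with no matching base record.
#'
#' @param panel A panel accepted by [validate_panel()].
#' @return A tibble of anomalies with columns `drug`, `date`, `anomaly`, and
#'   `message`; zero rows when no check fires.
#' @examples
#' qc_panel(paper_panel())
#' @export
qc_panel <- function(panel) {
  panel <- validate_panel(panel)
  empty <- tibble::tibble(
    drug = character(), date = as.Date(character()),
    anomaly = character(), message = character()
  )
  if (nrow(panel) == 0L) {
    return(empty)
  }
  wide <- tidyr::pivot_wider(
    panel,
    names_from = "kind", values_from = "count"
  )
  if (!"base" %in% names(wide)) wide$base <- NA_real_
  if (!"harm" %in% names(wide)) wide$harm <- NA_real_

  zero <- dplyr::filter(panel, .data$count == 0)
  exceeds <- dplyr::filter(
    wide, !is.na(.data$harm), !is.na(.data$base), .data$harm > .data$base
  )
  orphan <- dplyr::filter(wide, !is.na(.data$harm), is.na(.data$base))

  dplyr::bind_rows(
    empty,
    tibble::tibble(
      drug = zero$drug, date = zero$date, anomaly = "zero_count",
      message = sprintf("zero hit count for '%s' (%s)", zero$drug,
                        format(zero$date))
    ),
    tibble::tibble(
      drug = exceeds$drug, date = exceeds$date, anomaly = "harm_exceeds_base",
      message = sprintf(
        "harm count %s exceeds base count %s for '%s' (%s)",
        format(exceeds$harm, big.mark = ",", scientific = FALSE),
        format(exceeds$base, big.mark = ",", scientific = FALSE),
        exceeds$drug, format(exceeds$date)
      )
    ),
    tibble::tibble(
      drug = orphan$drug, date = orphan$date, anomaly = "missing_pair",
      message = sprintf("harm record without base record for '%s' (%s)",
                        orphan$drug, format(orphan$date))
    )
  ) |>
    dplyr::arrange(.data$drug, .data$date, .data$anomaly)
}
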