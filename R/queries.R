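#' Build a search query string for a drug
#'
#' Constructs the exact-phrase query used to obtain hit counts: the drug name
#' wrapped in double quotes, optionally conjoined with the harm-term
#' disjunction `"harm" OR "harmful"`. An optional cutoff date records the
#' "results available before" restriction of an advanced date-limited search;
#' it is carried as metadata only and does not alter the query string.
#'
#' @param drug_name Drug name (single string). Leading/trailing whitespace is
#'   trimmed; the trimmed name must be non-empty.
#' @param harm_variant If `TRUE`, render the harm-variant query used for the
#'   harm-index numerator.
#' @param before_date Optional cutoff [Date] (or string coercible to one)
#'   recording a date-restricted search.
#'
#' @return A one-row tibble with columns `drug_name`, `harm_variant`,
#'   `before_date`, and `rendered` (the final query string).
#' @examples
#' build_query("alcohol", harm_variant = TRUE)
#' build_query("cannabis")
#' @export
build_query <- function(drug_name, harm_variant = FALSE, before_date = NULL) {
  if (!is.character(drug_name) || length(drug_name) != 1L || is.na(drug_name)) {
    abort("`drug_name` must be a single non-missing string.")
  }
  drug_name <- trimws(drug_name)
  if (!nzchar(drug_name)) {
    abort("`drug_name` must be non-empty after trimming whitespace.")
  }
  stopifnot(is.logical(harm_variant), length(harm_variant) == 1L)
  rendered <- paste0('"', drug_name, '"')
  if (harm_variant) {
    rendered <- paste0(rendered, ' "harm" OR "harmful"')
  }
  before_date <- if (is.null(before_date)) as.Date(NA) else as.Date(before_date)
  tibble::tibble(
    drug_name = drug_name,
    harm_variant = harm_variant,
    before_date = before_date,
    rendered = rendered
  )
}

#' Screen candidate drug keywords
#'
#' Applies the keyword exclusion rules used when assembling the study list:
#' names made of two or more words give unreliable exact-phrase hit counts and
#' are excluded, and names on an ambiguity blocklist (terms that mostly return
#' pages about something other than the substance, such as the plant or animal
#' sense of a word) are excluded. Names are whitespace-trimmed and case-folded
#' to lower case before matching.
#'
#' @param drug_names Character vector of candidate names.
#' @param ambiguous_blocklist Character vector of names to exclude as
#'   ambiguous. Defaults to `c("tobacco", "mushrooms")`.
#'
#' @return A tibble with one row per input name, in input order, with columns
#'   `drug` (normalized name), `kept` (logical), and `reason` (`NA` for kept
#'   names, otherwise `"multi-word"` or `"ambiguous"`).
#' @examples
#' filter_keywords(c("cannabis", "anabolic steroids", "tobacco"))
#' @export
filter_keywords <- function(drug_names,
                            ambiguous_blocklist = c("tobacco", "mushrooms")) {
  stopifnot(is.character(drug_names))
  norm <- tolower(trimws(drug_names))
  blocklist <- tolower(trimws(ambiguous_blocklist))
  multi <- grepl("\\s", norm)
  ambiguous <- !multi & norm %in% blocklist
  tibble::tibble(
    drug = norm,
    kept = !multi & !ambiguous,
    reason = dplyr::case_when(
      multi ~ "multi-word",
      ambiguous ~ "ambiguous",
      TRUE ~ NA_character_
    )
  )
}
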