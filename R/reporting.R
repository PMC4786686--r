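#' Assemble a run configuration
#'
#' Bundles the inputs and settings of an end-to-end analysis run. Paths are
#' checked lazily at run time by the stages that need them.
#'
#' @param panel Path to a hit-count panel CSV (`drug,date,kind,count`), or a
#'   panel data frame.
#' @param harm_scores Path to a harm-score CSV (`drug,harm_score`), or a data
#'   frame; optional unless the validation stage runs.
#' @param trend_table Optional path to (or data frame of) an index table
#'   (`drug,date,index_percent`) for the trend stage; when absent,
#'   trajectories are computed from the panel if it covers several dates.
#' @param date Date to index; `NULL` uses the latest date in the panel.
#' @param threshold Co-variation threshold (default 0.9).
#' @param mode Co-variation mode, `"differences"` or `"levels"`.
#' @param rounding `"full"` or `"printed"` index precision for reports.
#' @param out_dir Output directory for written reports.
#' @param seed Integer seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters only when the panel is synthetic).
#' @param verbose Emit progress messages.
#' @return A `run_config` list.
#' @export
run_config <- function(panel, harm_scores = NULL, trend_table = NULL,
                       date = NULL, threshold = 0.9,
                       mode = c("differences", "levels"),
                       rounding = c("full", "printed"),
                       out_dir = tempfile("popharm-run-"),
                       seed = 1L, verbose = FALSE) {
  structure(
    list(
      panel = panel, harm_scores = harm_scores, trend_table = trend_table,
      date = if (is.null(date)) NULL else as.Date(date),
      threshold = threshold, mode = match.arg(mode),
      rounding = match.arg(rounding), out_dir = out_dir,
      seed = as.integer(seed), verbose = isTRUE(verbose)
    ),
    class = "run_config"
  )
}

resolve_table <- function(x, reader, what) {
  if (is.data.frame(x)) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) {
      abort(sprintf("%s file not found: %s", what, x))
    }
    return(reader(x))
  }
  abort(sprintf("`%s` must be a data frame or a file path.", what))
}

load_run_panel <- function(config) {
  panel <- resolve_table(config$panel, read_panel, "panel")
  validate_panel(panel)
}

run_date <- function(config, panel) {
  if (!is.null(config$date)) config$date else max(panel$date)
}

say <- function(config, fmt, ...) {
  if (config$verbose) inform(sprintf(fmt, ...))
}

#' Ranked popularity report
#'
#' Computes the popularity index at the configured date, ranks it, writes
#' `popularity.csv` (`rank,drug,count,index_percent`) to the output directory,
#' and logs the reference (maximum) drug and date.
#'
#' @param config A [run_config()].
#' @return The ranked popularity tibble, invisibly; the written file path is
#'   in the `path` attribute.
#' @examples
#' cfg <- run_config(paper_panel(), rounding = "printed",
#'                   out_dir = tempfile())
#' head(run_popularity(cfg))
#' @export
run_popularity <- function(config) {
  stopifnot(inherits(config, "run_config"))
  panel <- load_run_panel(config)
  if (nrow(panel) == 0L) {
    abort("The panel is empty; nothing to rank.")
  }
  date <- run_date(config, panel)
  pop <- popularity_index(panel, date, rounding = config$rounding)
  ranked <- rank_table(pop, "popularity") |>
    dplyr::left_join(dplyr::select(pop, "drug", "count"), by = "drug") |>
    dplyr::select("rank", "drug", "count", index_percent = "value")
  say(config, "Popularity at %s: reference drug '%s' (count %s).",
      format(date), attr(pop, "max_drug"),
      format(max(pop$count), big.mark = ",", scientific = FALSE))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, "popularity.csv")
  readr::write_csv(ranked, path)
  attr(ranked, "path") <- path
  invisible(ranked)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one configuration: loads and quality-checks
#' the panel, computes ranked popularity and harm tables at the target date,
#' assembles popularity trajectories and their co-variation groups and rank
#' crossings (when more than one date is available), validates the harm index
#' against external harm scores (when provided), and writes every report plus
#' a JSON manifest (`manifest.json`) listing the configuration, the QC
#' anomalies, and every file written. Any stage failure aborts with the stage
#' named; QC anomalies are reported, never silently dropped.
#'
#' @param config A [run_config()].
#' @return A list with elements `popularity`, `harm`, `qc`, `covariation`
#'   (or `NULL`), `crossings` (or `NULL`), `validation` (or `NULL`), and
#'   `manifest`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
  }

  panel <- stage("load", load_run_panel(config))
  if (nrow(panel) == 0L) {
    abort("Stage 'load' failed: the panel is empty.")
  }
  date <- run_date(config, panel)

  qc <- stage("qc", qc_panel(panel))
  for (msg in qc$message) warn(paste0("QC anomaly: ", msg))
  qc_path <- file.path(config$out_dir, "qc_report.csv")
  readr::write_csv(qc, qc_path)
  files <- c(files, qc_path)

  popularity <- stage("popularity", run_popularity(config))
  files <- c(files, attr(popularity, "path"))

  harm_tab <- stage("harm", {
    h <- harm_index(panel, date, rounding = config$rounding)
    rank_table(h, "harm") |>
      dplyr::left_join(dplyr::select(h, "drug", "base_count", "harm_count"),
                       by = "drug") |>
      dplyr::select("rank", "drug", "base_count", "harm_count",
                    harm_index_percent = "value")
  })
  harm_path <- file.path(config$out_dir, "harm.csv")
  readr::write_csv(harm_tab, harm_path)
  files <- c(files, harm_path)

  trend_input <- if (!is.null(config$trend_table)) {
    stage("trends", resolve_table(config$trend_table, read_index_table,
                                  "trend_table"))
  } else if (length(unique(panel$date)) >= 3L) {
    stage("trends", {
      purrr::map(sort(unique(panel$date)),
                 \(d) popularity_index(panel, d)) |>
        purrr::list_rbind() |>
        dplyr::select("drug", "date", "index_percent")
    })
  } else {
    NULL
  }
  cov <- NULL
  crossings <- NULL
  if (!is.null(trend_input)) {
    cov <- stage("trends", covariation(trend_input, config$threshold,
                                       config$mode))
    pair_path <- file.path(config$out_dir, "covariation_pairs.csv")
    readr::write_csv(tidy(cov), pair_path)
    group_path <- file.path(config$out_dir, "covariation_groups.json")
    jsonlite::write_json(
      list(threshold = cov$threshold, mode = cov$mode,
           excluded = cov$excluded, groups = cov$groups),
      group_path, auto_unbox = TRUE, pretty = TRUE
    )
    files <- c(files, pair_path, group_path)

    crossings <- stage("trends", {
      drugs <- sort(unique(trend_input$drug))
      combos <- utils::combn(drugs, 2L, simplify = FALSE)
      purrr::map(combos, function(pr) {
        detect_crossings(build_series(trend_input, pr[[1L]]),
                         build_series(trend_input, pr[[2L]]))
      }) |>
        purrr::list_rbind()
    })
    cross_path <- file.path(config$out_dir, "rank_crossings.csv")
    readr::write_csv(crossings, cross_path)
    files <- c(files, cross_path)
  }

  validation <- NULL
  if (!is.null(config$harm_scores)) {
    validation <- stage("validation", {
      scores <- resolve_table(config$harm_scores, read_harm_scores,
                              "harm_scores")
      validate_harm(harm_index(panel, date), scores,
                    use_printed_rounding = config$rounding == "printed")
    })
    val_path <- file.path(config$out_dir, "validation.json")
    jsonlite::write_json(
      glance(validation), val_path, auto_unbox = TRUE, digits = NA,
      dataframe = "rows", pretty = TRUE
    )
    files <- c(files, val_path)
  }

  manifest <- list(
    package = "popharm",
    version = as.character(utils::packageVersion("popharm")),
    config = list(
      date = format(date), threshold = config$threshold, mode = config$mode,
      rounding = config$rounding, seed = config$seed
    ),
    n_drugs = length(unique(panel$drug)),
    n_dates = length(unique(panel$date)),
    n_validation_pairs = if (is.null(validation)) NULL else validation$n,
    qc_anomalies = qc$message,
    files = basename(files)
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say(config, "Wrote %d file(s) to %s.", length(files) + 1L, config$out_dir)

  list(popularity = popularity, harm = harm_tab, qc = qc,
       covariation = cov, crossings = crossings, validation = validation,
       manifest = manifest)
}
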