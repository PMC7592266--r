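# Readers and writers for the package's plain-CSV interfaces. All tabular
# inputs use fixed headers; there is no dialect sniffing.

read_strict_csv <- function(path, columns) {
  if (!file.exists(path)) {
    stop_config(sprintf("file not found: '%s'", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(columns, names(df))
  extra <- setdiff(names(df), columns)
  if (length(missing) || length(extra)) {
    stop_data(sprintf(
      "'%s' must have exactly the columns [%s]%s%s",
      path, paste(columns, collapse = ", "),
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")) else ""
    ))
  }
  df[columns]
}

needs_columns <- c(
  "inn", "route", "unit_kind", "scope", "total_amount", "total_lb",
  "total_ub", "smallest_units", "units_lb", "units_ub"
)

#' Read a need-estimate table
#'
#' The on-disk counterpart of [aggregate_need()]'s output (see
#' [write_needs()]); also the format in which externally estimated needs —
#' e.g. published unit totals — enter the budget and comparison paths when
#' course-level dose schedules are not available.
#'
#' @param path Path to a CSV file.
#' @return A need tibble.
#' @export
read_needs <- function(path) {
  n <- read_strict_csv(path, needs_columns)
  if (any(n$total_amount < 0 | n$smallest_units < 0)) {
    stop_data(sprintf("negative amounts in needs file '%s'", path))
  }
  n$formulation <- formulation_label(n$inn, n$route)
  tibble::as_tibble(n[c("formulation", setdiff(needs_columns, "formulation"))])
}

#' Write a need-estimate table
#'
#' @param needs Need tibble, as from [aggregate_need()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_needs <- function(needs, path) {
  utils::write.csv(as.data.frame(needs)[needs_columns], path, row.names = FALSE)
  invisible(path)
}

#' Write a budget report
#'
#' Mirrors the layout of a published expenditure table: one row per
#' formulation, then class subtotals, the grand total and — when available —
#' the health-expenditure share.
#'
#' @param report A `budget_report`.
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_budget_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    out <- list(
      scope = report$scope,
      items = as.data.frame(report$items),
      subtotal_antineoplastic = report$subtotal_antineoplastic,
      subtotal_chemoprotective = report$subtotal_chemoprotective,
      total = report$total,
      total_lb = report$total_lb,
      total_ub = report$total_ub,
      health_expenditure_usd = report$health_expenditure_usd,
      health_expenditure_share_pct = report$health_expenditure_share_pct
    )
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
    return(invisible(path))
  }
  it <- report$items
  rows <- data.frame(
    row_type = "formulation",
    formulation = it$formulation,
    drug_class = it$drug_class,
    smallest_units = it$smallest_units,
    cost_usd = it$cost_usd,
    share_pct = round(it$share_pct, 1),
    stringsAsFactors = FALSE
  )
  summary_rows <- data.frame(
    row_type = c("subtotal_antineoplastic", "subtotal_chemoprotective", "total"),
    formulation = NA_character_,
    drug_class = c("antineoplastic", "chemoprotective", NA),
    smallest_units = NA_real_,
    cost_usd = c(report$subtotal_antineoplastic, report$subtotal_chemoprotective,
                 report$total),
    share_pct = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(report$health_expenditure_share_pct)) {
    summary_rows <- rbind(summary_rows, data.frame(
      row_type = "health_expenditure_share", formulation = NA, drug_class = NA,
      smallest_units = NA_real_,
      cost_usd = NA_real_,
      share_pct = round(report$health_expenditure_share_pct, 3)
    ))
  }
  utils::write.csv(rbind(rows, summary_rows), path, row.names = FALSE)
  invisible(path)
}

#' Path to the packaged Thai 2017 case-study fixture
#'
#' The fixture encodes a published Thai 2017 paediatric-ALL case study at the
#' level its tables print: age-stratified incidence with uncertainty bounds,
#' risk and relapse stratification parameters, smallest-unit counts needed
#' and sold, derived unit prices, and national health expenditure. See the
#' fixture's own README for which numbers are published and which are
#' derived or synthetic.
#'
#' @param ... Path components below the fixture directory.
#' @return A file path.
#' @export
thai_fixture_path <- function(...) {
  p <- system.file("extdata", "thai_all_2017", ..., package = "allquant",
                   mustWork = TRUE)
  p
}

#' Copy the packaged fixture to a directory
#'
#' @param dir Target directory (created if absent).
#' @return `dir`, invisibly.
#' @export
copy_fixture <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  src <- list.files(thai_fixture_path(), full.names = TRUE)
  ok <- file.copy(src, dir, overwrite = TRUE)
  if (!all(ok)) stop_data(sprintf("could not copy fixture files to '%s'", dir))
  invisible(dir)
}
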