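#' Read a unit price list
#'
#' List prices in US$ per smallest dispensing unit, one row per formulation
#' and price year. Columns (exact header match): `inn`, `route`,
#' `smallest_unit_strength`, `unit_price_usd`, `price_year`.
#'
#' @param path Path to a CSV file.
#' @return A tibble of price entries.
#' @export
read_prices <- function(path) {
  cols <- c("inn", "route", "smallest_unit_strength", "unit_price_usd", "price_year")
  p <- read_strict_csv(path, cols)
  if (any(p$unit_price_usd < 0)) {
    stop_data(sprintf("negative unit price in '%s'", path))
  }
  if (anyDuplicated(p[c("inn", "route", "price_year")])) {
    stop_data(sprintf("duplicate (inn, route, price_year) price entries in '%s'", path))
  }
  p$formulation <- formulation_label(p$inn, p$route)
  tibble::as_tibble(p)
}

#' Adjust prices for inflation
#'
#' Compounds each unit price by `(1 + annual_rate)^(to_year - from_year)` and
#' restamps the price year.
#'
#' @param prices Price tibble, as from [read_prices()].
#' @param annual_rate Annual inflation rate (e.g. `0.03` for 3%); `> -1`.
#' @param from_year,to_year Calendar years; `to_year >= from_year`.
#' @return The price tibble with adjusted `unit_price_usd` and `price_year`.
#' @export
inflate_prices <- function(prices, annual_rate, from_year, to_year) {
  if (to_year < from_year) stop_usage("to_year must be >= from_year")
  if (annual_rate <= -1) stop_validation("annual_rate must be > -1")
  prices$unit_price_usd <- prices$unit_price_usd * (1 + annual_rate)^(to_year - from_year)
  prices$price_year <- to_year
  prices
}

#' Budget report: expenditure to purchase the needed units
#'
#' Per-formulation cost is `smallest_units * unit_price`; costs are
#' sub-totalled by drug class (antineoplastic vs chemoprotective) and summed
#' to a grand total, with each formulation's percentage share of the total.
#' List prices make the result a conservative (maximum) estimate of the
#' budget needed. If `health_expenditure_usd` is supplied the report also
#' carries the total's share of national health expenditure.
#'
#' @param needs Need tibble, as from [aggregate_need()] or [read_needs()].
#' @param prices Price tibble, as from [read_prices()].
#' @param protocols A `protocol_set` (source of drug classes and routes).
#' @param health_expenditure_usd Optional national health expenditure (US$).
#' @return A `budget_report`: list with an `items` tibble, class subtotals,
#'   `total`, bound totals, and (optionally) `health_expenditure_share_pct`.
#' @export
expenditure <- function(needs, prices, protocols, health_expenditure_usd = NULL) {
  needs <- needs[needs$smallest_units > 0 | needs$total_amount > 0, , drop = FALSE]
  i <- match(needs$formulation, prices$formulation)
  if (anyNA(i)) {
    stop_data(sprintf(
      "no price for formulation(s): %s",
      paste(needs$formulation[is.na(i)], collapse = ", ")
    ))
  }
  j <- match(needs$formulation, protocols$formulary$formulation)
  if (anyNA(j)) {
    stop_data(sprintf(
      "formulation(s) absent from formulary: %s",
      paste(needs$formulation[is.na(j)], collapse = ", ")
    ))
  }
  items <- tibble::tibble(
    formulation = needs$formulation,
    inn = needs$inn,
    route = needs$route,
    drug_class = protocols$formulary$drug_class[j],
    parenteral = protocols$formulary$parenteral[j],
    smallest_units = needs$smallest_units,
    unit_price_usd = prices$unit_price_usd[i],
    cost_usd = needs$smallest_units * prices$unit_price_usd[i],
    cost_lb = needs$units_lb * prices$unit_price_usd[i],
    cost_ub = needs$units_ub * prices$unit_price_usd[i]
  )
  total <- sum(items$cost_usd)
  items$share_pct <- if (total > 0) 100 * items$cost_usd / total else 0
  report <- structure(list(
    items = items,
    subtotal_antineoplastic = sum(items$cost_usd[items$drug_class == "antineoplastic"]),
    subtotal_chemoprotective = sum(items$cost_usd[items$drug_class == "chemoprotective"]),
    total = total,
    total_lb = sum(items$cost_lb),
    total_ub = sum(items$cost_ub),
    scope = if (nrow(needs)) needs$scope[1] else NA_character_,
    health_expenditure_usd = health_expenditure_usd,
    health_expenditure_share_pct = NULL
  ), class = "budget_report")
  if (!is.null(health_expenditure_usd)) {
    report$health_expenditure_share_pct <-
      health_expenditure_share(total, health_expenditure_usd)
  }
  report
}

#' @export
print.budget_report <- function(x, ...) {
  cat(sprintf("<budget_report> scope: %s\n", x$scope))
  it <- x$items[order(-x$items$cost_usd), ]
  cat(sprintf(
    "  %-28s %14s %12s %7s\n", "formulation", "units", "cost (US$)", "share"
  ))
  for (k in seq_len(nrow(it))) {
    cat(sprintf(
      "  %-28s %14s %12s %6.1f%%\n",
      it$formulation[k],
      format(round_half_away(it$smallest_units[k]), big.mark = " "),
      format(round_half_away(it$cost_usd[k]), big.mark = " "),
      it$share_pct[k]
    ))
  }
  cat(sprintf("  antineoplastic subtotal:  US$ %s\n",
              format(round_half_away(x$subtotal_antineoplastic), big.mark = " ")))
  cat(sprintf("  chemoprotective subtotal: US$ %s\n",
              format(round_half_away(x$subtotal_chemoprotective), big.mark = " ")))
  cat(sprintf("  total:                    US$ %s\n",
              format(round_half_away(x$total), big.mark = " ")))
  if (!is.null(x$health_expenditure_share_pct)) {
    cat(sprintf("  share of health expenditure: %.3f%%\n",
                x$health_expenditure_share_pct))
  }
  invisible(x)
}

#' Share of national health expenditure
#'
#' `100 * total / national_health_expenditure`, in percent. Reporting rounds
#' to three decimal places.
#'
#' @param total Expenditure in US$.
#' @param national_health_expenditure National health expenditure in US$,
#'   strictly positive.
#' @return Percentage (unrounded).
#' @export
health_expenditure_share <- function(total, national_health_expenditure) {
  if (!is.finite(national_health_expenditure) || national_health_expenditure <= 0) {
    stop_domain("national_health_expenditure must be strictly positive")
  }
  100 * total / national_health_expenditure
}

#' Additional cost of vial wastage
#'
#' When vial sizes exceed administered doses, part of each parenteral vial is
#' discarded. The surcharge is modelled as an additive fraction of the
#' expenditure on parenteral (vial-administered) formulations; oral
#' formulations carry no wastage.
#'
#' @param report A `budget_report`.
#' @param wastage_fraction Fraction of vial content wasted, in `[0, 1]`.
#' @return Additional cost in US$.
#' @export
vial_wastage_cost <- function(report, wastage_fraction) {
  if (!is.finite(wastage_fraction) || wastage_fraction < 0 || wastage_fraction > 1) {
    stop_validation("wastage_fraction must lie in [0, 1]")
  }
  parenteral_cost <- sum(report$items$cost_usd[report$items$parenteral])
  wastage_fraction * parenteral_cost
}
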