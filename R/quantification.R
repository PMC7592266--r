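#' Aggregate national medicine need across cohorts
#'
#' Multiplies each cohort's (possibly fractional) patient count by the
#' per-patient course requirement for its protocol arm, evaluated at the
#' cohort's band-mean BSA (and band-mean weight for any `per_kg` rule), then
#' sums over cohorts per formulation. Uncertainty bounds are computed
#' identically from the cohort count bounds. The milligram (or active-unit)
#' totals are converted to smallest dispensing units under a rounding policy:
#'
#' * `"aggregate"` (default): ceiling of the national total per formulation —
#'   the total procured stock must cover the total amount needed.
#' * `"per_patient"`: each child's course is rounded up to whole units before
#'   summation — the operationally conservative variant in which no child's
#'   course is split across a shared unit.
#'
#' @param cohorts Cohort tibble (initial and/or relapse arms) of one scope.
#' @param protocols A `protocol_set`.
#' @param anthropometry Anthropometric reference, as from
#'   [read_anthropometry()].
#' @param unit_policy Smallest-unit rounding policy, see above.
#' @return A need tibble with one row per formulation: `formulation`, `inn`,
#'   `route`, `unit_kind`, `scope`, `total_amount`, `total_lb`, `total_ub`,
#'   `smallest_units`, `units_lb`, `units_ub`.
#' @export
aggregate_need <- function(cohorts, protocols, anthropometry,
                           unit_policy = c("aggregate", "per_patient")) {
  unit_policy <- match.arg(unit_policy)
  if (length(unique(cohorts$scope)) > 1) {
    stop_usage("aggregate_need() expects cohorts of a single population scope")
  }
  missing_arm <- setdiff(unique(cohorts$arm), unique(protocols$rules$arm))
  if (length(missing_arm)) {
    stop_config(sprintf(
      "cohort arm(s) without a protocol: %s", paste(missing_arm, collapse = ", ")
    ))
  }
  form <- protocols$formulary
  zero <- stats::setNames(numeric(nrow(form)), form$formulation)
  total <- total_lb <- total_ub <- zero
  per_patient_units <- per_patient_units_lb <- per_patient_units_ub <- zero
  strength <- stats::setNames(form$smallest_unit_strength, form$formulation)
  for (k in seq_len(nrow(cohorts))) {
    band <- cohorts$age_band[k]
    bsa <- mean_bsa_for_band(anthropometry, band)
    w <- anthropometry$mean_weight_kg[match(band, anthropometry$age_band)]
    req <- per_patient_requirement(protocols, cohorts$arm[k], band, bsa, w)
    idx <- names(req)
    total[idx] <- total[idx] + cohorts$count[k] * req
    total_lb[idx] <- total_lb[idx] + cohorts$count_lb[k] * req
    total_ub[idx] <- total_ub[idx] + cohorts$count_ub[k] * req
    if (unit_policy == "per_patient") {
      per_course_units <- ceiling(req / strength[idx] - 1e-9)
      per_patient_units[idx] <- per_patient_units[idx] +
        cohorts$count[k] * per_course_units
      per_patient_units_lb[idx] <- per_patient_units_lb[idx] +
        cohorts$count_lb[k] * per_course_units
      per_patient_units_ub[idx] <- per_patient_units_ub[idx] +
        cohorts$count_ub[k] * per_course_units
    }
  }
  if (unit_policy == "aggregate") {
    units <- to_smallest_units(total, strength)
    units_lb <- to_smallest_units(total_lb, strength)
    units_ub <- to_smallest_units(total_ub, strength)
  } else {
    units <- ceiling(per_patient_units - 1e-9)
    units_lb <- ceiling(per_patient_units_lb - 1e-9)
    units_ub <- ceiling(per_patient_units_ub - 1e-9)
  }
  tibble::tibble(
    formulation = form$formulation,
    inn = form$inn,
    route = form$route,
    unit_kind = form$unit_kind,
    scope = if (nrow(cohorts)) cohorts$scope[1] else NA_character_,
    total_amount = as.numeric(total),
    total_lb = as.numeric(total_lb),
    total_ub = as.numeric(total_ub),
    smallest_units = as.numeric(units),
    units_lb = as.numeric(units_lb),
    units_ub = as.numeric(units_ub)
  )
}

#' Convert an aggregate amount to smallest dispensing units
#'
#' Ceiling division by the smallest-unit strength: procurement cannot buy a
#' fraction of a dispensing unit, and the procured stock must cover the full
#' amount needed. A small tolerance absorbs floating-point noise so that exact
#' multiples do not round up an extra unit.
#'
#' @param total_amount Amount needed (mg or active units), `>= 0`; vectorised.
#' @param smallest_unit_strength Active ingredient per smallest unit, `> 0`.
#' @return Integer-valued numeric vector of smallest units.
#' @export
to_smallest_units <- function(total_amount, smallest_unit_strength) {
  if (any(!is.finite(smallest_unit_strength) | smallest_unit_strength <= 0)) {
    stop_validation("smallest_unit_strength must be strictly positive")
  }
  if (any(!is.finite(total_amount) | total_amount < 0)) {
    stop_validation("total_amount must be non-negative and finite")
  }
  ceiling(total_amount / smallest_unit_strength - 1e-9)
}

#' Read pack-level sales records
#'
#' Columns (exact header match): `inn`, `route`, `strength`, `strength_unit`,
#' `units_per_pack`, `packs_sold`, `quarter` (format `YYYY-Qn`).
#'
#' @param path Path to a CSV file.
#' @return A tibble of sales records with a derived `year` column.
#' @export
read_sales <- function(path) {
  cols <- c("inn", "route", "strength", "strength_unit",
            "units_per_pack", "packs_sold", "quarter")
  s <- read_strict_csv(path, cols)
  if (any(s$strength <= 0 | s$units_per_pack <= 0 | s$packs_sold < 0)) {
    stop_data(sprintf("non-positive strength/pack fields in sales file '%s'", path))
  }
  if (!all(grepl("^[0-9]{4}-Q[1-4]$", s$quarter))) {
    stop_data(sprintf("sales quarters in '%s' must have format YYYY-Qn", path))
  }
  s$year <- as.integer(substr(s$quarter, 1, 4))
  tibble::as_tibble(s)
}

#' Convert sales records to smallest units and total amount
#'
#' For one formulation, sums `packs_sold * units_per_pack * strength` over the
#' matching records of the target year (total mg or active units sold), then
#' converts to smallest dispensing units by *floor* division: sold physical
#' stock cannot exceed its actual active-ingredient content. Records whose
#' `inn` is not in the formulary are skipped with a warning; a record matching
#' the formulation but carrying the wrong strength unit (mg vs active units)
#' is a hard error.
#'
#' @param sales Sales tibble, as from [read_sales()].
#' @param formulation One row of a `protocol_set` formulary (or a list with
#'   `inn`, `route`, `unit_kind`, `smallest_unit_strength`).
#' @param year Calendar year to which records are restricted.
#' @param known_inns Character vector of formulary medicine names used to
#'   decide which unmatched records deserve a warning (default: the
#'   formulation's own inn only).
#' @return A list with `total_amount` and `units`.
#' @export
sales_to_units <- function(sales, formulation, year, known_inns = formulation$inn) {
  unknown <- !sales$inn %in% known_inns
  if (any(unknown)) {
    warning(sprintf(
      "skipping %d sales record(s) with unknown inn: %s",
      sum(unknown), paste(unique(sales$inn[unknown]), collapse = ", ")
    ), call. = FALSE)
  }
  sel <- sales$inn == formulation$inn & sales$route == formulation$route &
    sales$year == year
  rec <- sales[sel, , drop = FALSE]
  if (any(rec$strength_unit != formulation$unit_kind)) {
    stop_data(sprintf(
      "strength unit mismatch for %s: sales record in '%s', formulation in '%s'",
      formulation_label(formulation$inn, formulation$route),
      paste(unique(rec$strength_unit[rec$strength_unit != formulation$unit_kind]),
            collapse = ", "),
      formulation$unit_kind
    ))
  }
  total <- sum(rec$packs_sold * rec$units_per_pack * rec$strength)
  list(
    total_amount = total,
    units = floor(total / formulation$smallest_unit_strength + 1e-9)
  )
}

#' Sufficiency ratio of sold to needed units
#'
#' `sold / needed`, both in smallest dispensing units of the same
#' formulation. A ratio above 1 means the market supplied more than the
#' estimated national need. Reporting rounds to one decimal.
#'
#' @param sold_units Units sold.
#' @param needed_units Units needed; must be strictly positive.
#' @return The ratio as a real number (unrounded).
#' @export
sufficiency_ratio <- function(sold_units, needed_units) {
  if (any(needed_units <= 0)) {
    stop_domain("sufficiency ratio undefined: needed_units must be > 0")
  }
  sold_units / needed_units
}

#' Compare estimated need with market sales
#'
#' Restricted to formulations flagged `predominantly_paediatric_all` in the
#' formulary: for other medicines the market volume is dominated by adult
#' indications and a need-vs-sales ratio would not be informative.
#'
#' @param needs Need tibble, as from [aggregate_need()] or [read_needs()].
#' @param sales Sales tibble, as from [read_sales()].
#' @param protocols A `protocol_set` (source of the formulary and flags).
#' @param year Calendar year of the comparison.
#' @return A tibble with `formulation`, `inn`, `route`, `needed_units`,
#'   `sold_units`, `ratio` and `ratio_reported` (one decimal).
#' @export
compare_sales_to_need <- function(needs, sales, protocols, year) {
  form <- protocols$formulary
  form <- form[form$predominantly_paediatric_all, , drop = FALSE]
  if (nrow(form) == 0) {
    stop_config("no formulation is flagged predominantly_paediatric_all")
  }
  known <- protocols$medicines$inn
  rows <- lapply(seq_len(nrow(form)), function(i) {
    f <- form[i, , drop = FALSE]
    sold <- sales_to_units(sales, f, year, known_inns = known)
    j <- match(f$formulation, needs$formulation)
    if (is.na(j)) {
      stop_data(sprintf("no need estimate for formulation '%s'", f$formulation))
    }
    needed <- needs$smallest_units[j]
    ratio <- sufficiency_ratio(sold$units, needed)
    tibble::tibble(
      formulation = f$formulation, inn = f$inn, route = f$route,
      needed_units = needed, sold_units = sold$units,
      ratio = ratio, ratio_reported = round(ratio, 1)
    )
  })
  dplyr::bind_rows(rows)
}
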