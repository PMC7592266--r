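#' Read age-stratified incidence estimates
#'
#' One row per calendar year and age band, carrying point estimates and 95%
#' uncertainty bounds for diagnosed and undiagnosed incident cases. Counts may
#' be fractional: incidence models produce non-integer expected case numbers,
#' and all internal arithmetic keeps the fractions (rounding is a display
#' concern, see [report_counts()]).
#'
#' Columns (exact header match): `year`, `age_band`, `diagnosed`,
#' `diagnosed_lb`, `diagnosed_ub`, `undiagnosed`, `undiagnosed_lb`,
#' `undiagnosed_ub`.
#'
#' @param path Path to a CSV file.
#' @return A tibble of incidence estimates.
#' @export
read_incidence <- function(path) {
  cols <- c(
    "year", "age_band", "diagnosed", "diagnosed_lb", "diagnosed_ub",
    "undiagnosed", "undiagnosed_lb", "undiagnosed_ub"
  )
  inc <- read_strict_csv(path, cols)
  inc$age_band <- as.character(inc$age_band)
  for (stem in c("diagnosed", "undiagnosed")) {
    n <- inc[[stem]]
    lb <- inc[[paste0(stem, "_lb")]]
    ub <- inc[[paste0(stem, "_ub")]]
    if (any(n < 0 | lb < 0 | ub < 0)) {
      stop_data(sprintf("negative %s counts in '%s'", stem, path))
    }
    if (any(lb > n + 1e-9 | n > ub + 1e-9)) {
      stop_data(sprintf(
        "bound ordering violated for %s in '%s' (need lb <= point <= ub)",
        stem, path
      ))
    }
  }
  if (anyDuplicated(inc[c("year", "age_band")])) {
    stop_data(sprintf("duplicate (year, age_band) rows in '%s'", path))
  }
  tibble::as_tibble(inc)
}

normalize_scope <- function(scope) {
  if (length(scope) != 1 || !is.character(scope)) {
    stop_config("scope must be a single string")
  }
  aliases <- c(
    diagnosed = "diagnosed", dx = "diagnosed",
    diagnosed_plus_undiagnosed = "diagnosed_plus_undiagnosed",
    `dx+udx` = "diagnosed_plus_undiagnosed",
    combined = "diagnosed_plus_undiagnosed"
  )
  if (!scope %in% names(aliases)) {
    stop_config(sprintf(
      "unknown population scope '%s' (expected one of: %s)",
      scope, paste(names(aliases), collapse = ", ")
    ))
  }
  unname(aliases[[scope]])
}

#' Select the population scope of an incidence table
#'
#' Collapses the diagnosed / undiagnosed columns to one scoped count per age
#' band: the `"diagnosed"` scope keeps diagnosed counts, the combined scope
#' (`"diagnosed_plus_undiagnosed"`, aliases `"dx+udx"` and `"combined"`) adds
#' undiagnosed counts component-wise, bounds included.
#'
#' @param incidence Incidence tibble, as from [read_incidence()].
#' @param scope Population scope label.
#' @param year Optional calendar year filter; required when `incidence` spans
#'   several years.
#' @return A tibble with columns `age_band`, `scope`, `count`, `count_lb`,
#'   `count_ub`.
#' @export
scope_population <- function(incidence, scope, year = NULL) {
  scope <- normalize_scope(scope)
  if (!is.null(year)) {
    incidence <- incidence[incidence$year == year, , drop = FALSE]
    if (nrow(incidence) == 0) {
      stop_data(sprintf("no incidence rows for year %s", year))
    }
  } else if (length(unique(incidence$year)) > 1) {
    stop_usage("incidence spans several years; pass an explicit 'year'")
  }
  add_und <- scope == "diagnosed_plus_undiagnosed"
  tibble::tibble(
    age_band = incidence$age_band,
    scope = scope,
    count = incidence$diagnosed + if (add_und) incidence$undiagnosed else 0,
    count_lb = incidence$diagnosed_lb +
      if (add_und) incidence$undiagnosed_lb else 0,
    count_ub = incidence$diagnosed_ub +
      if (add_und) incidence$undiagnosed_ub else 0
  )
}

#' Stratify scoped incidence into standard- and high-risk cohorts
#'
#' Splits each band's scoped count by the band's standard-risk fraction; the
#' high-risk cohort is the complement. Fractional counts are retained and
#' uncertainty bounds are scaled by the same fractions, so conservation
#' (standard + high = band count) holds exactly, pre-rounding.
#'
#' @param scoped Scoped counts, as from [scope_population()].
#' @param risk_rules A data frame with columns `age_band` and
#'   `standard_fraction` (in `[0, 1]`), one row per band.
#' @return A cohort tibble with columns `age_band`, `arm` (`"standard"` /
#'   `"high"`), `scope`, `count`, `count_lb`, `count_ub`.
#' @export
stratify_risk <- function(scoped, risk_rules) {
  if (anyDuplicated(risk_rules$age_band)) {
    stop_config("duplicate risk rules for one age band")
  }
  if (any(risk_rules$standard_fraction < 0 | risk_rules$standard_fraction > 1)) {
    stop_validation("standard_fraction outside [0, 1] in risk rules")
  }
  i <- match(scoped$age_band, risk_rules$age_band)
  if (anyNA(i)) {
    stop_config(sprintf(
      "no risk rule for age band(s): %s",
      paste(scoped$age_band[is.na(i)], collapse = ", ")
    ))
  }
  f <- risk_rules$standard_fraction[i]
  std <- scoped
  std$arm <- "standard"
  std$count <- scoped$count * f
  std$count_lb <- scoped$count_lb * f
  std$count_ub <- scoped$count_ub * f
  high <- scoped
  high$arm <- "high"
  high$count <- scoped$count - std$count
  high$count_lb <- scoped$count_lb - std$count_lb
  high$count_ub <- scoped$count_ub - std$count_ub
  out <- dplyr::bind_rows(std, high)
  out[c("age_band", "arm", "scope", "count", "count_lb", "count_ub")]
}

#' Apply the relapse cascade to initial-course cohorts
#'
#' A fraction of the scoped incident population relapses and receives a second
#' course of treatment. Relapsed children undergo an independent second risk
#' assessment, so the relapse split (`standard_relapse_fraction` and its
#' complement) does not depend on the initial risk arm. The relapse pool is
#' distributed over age bands in proportion to each band's initial count, and
#' uncertainty bounds are scaled proportionally.
#'
#' @param cohorts Initial-course cohorts of a single scope, as from
#'   [stratify_risk()].
#' @param relapse_fraction Fraction of the scoped incident population that
#'   relapses, in `[0, 1]`.
#' @param standard_relapse_fraction Fraction of relapses treated on the
#'   standard-risk relapse protocol, in `[0, 1]`; the complement is treated on
#'   the high-risk relapse protocol.
#' @return A cohort tibble with arms `"relapse_standard"` and
#'   `"relapse_high"`, same columns as [stratify_risk()].
#' @export
apply_relapse <- function(cohorts, relapse_fraction, standard_relapse_fraction) {
  if (relapse_fraction < 0 || relapse_fraction > 1) {
    stop_validation("relapse_fraction outside [0, 1]")
  }
  if (standard_relapse_fraction < 0 || standard_relapse_fraction > 1) {
    stop_validation("standard_relapse_fraction outside [0, 1]")
  }
  if (length(unique(cohorts$scope)) > 1) {
    stop_usage("apply_relapse() expects cohorts of a single population scope")
  }
  if (!all(cohorts$arm %in% c("standard", "high"))) {
    stop_usage("apply_relapse() expects initial-course cohorts (arms standard/high)")
  }
  if (relapse_fraction == 0) {
    return(cohorts[0, , drop = FALSE])
  }
  by_band <- dplyr::summarise(
    dplyr::group_by(cohorts, .data$age_band, .data$scope),
    count = sum(.data$count),
    count_lb = sum(.data$count_lb),
    count_ub = sum(.data$count_ub),
    .groups = "drop"
  )
  split_one <- function(arm, frac) {
    out <- by_band
    out$arm <- arm
    out$count <- by_band$count * relapse_fraction * frac
    out$count_lb <- by_band$count_lb * relapse_fraction * frac
    out$count_ub <- by_band$count_ub * relapse_fraction * frac
    out
  }
  out <- dplyr::bind_rows(
    split_one("relapse_standard", standard_relapse_fraction),
    split_one("relapse_high", 1 - standard_relapse_fraction)
  )
  out[c("age_band", "arm", "scope", "count", "count_lb", "count_ub")]
}

#' Display table of cohort counts
#'
#' Rounds counts and bounds to the nearest integer, half away from zero, for
#' reporting. Internal fractional values are never modified; published tables
#' round this way, which is why printed sub-totals can disagree with printed
#' cell sums by one.
#'
#' @param cohorts A cohort tibble.
#' @return The same tibble with `count`, `count_lb`, `count_ub` rounded to
#'   integers.
#' @export
report_counts <- function(cohorts) {
  for (col in c("count", "count_lb", "count_ub")) {
    cohorts[[col]] <- round_half_away(cohorts[[col]])
  }
  cohorts
}
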