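#' Build the treatable cohorts of a run
#'
#' Scope selection, risk stratification and the relapse cascade in one step:
#' the full set of initial-course and relapse cohorts for one population
#' scope, with uncertainty bounds.
#'
#' @param config A `run_config`.
#' @param scope Population scope (defaults to the config's).
#' @param bound Which incidence estimate drives the point counts: the point
#'   estimate (default) or the lower/upper uncertainty bound.
#' @return A cohort tibble with arms `standard`, `high`, `relapse_standard`,
#'   `relapse_high`.
#' @export
build_cohorts <- function(config, scope = config$scope,
                          bound = c("point", "lower", "upper")) {
  bound <- match.arg(bound)
  scoped <- scope_population(config$incidence, scope, config$year)
  if (bound == "lower") scoped$count <- scoped$count_lb
  if (bound == "upper") scoped$count <- scoped$count_ub
  initial <- stratify_risk(scoped, config$risk_rules)
  relapse <- apply_relapse(
    initial, config$relapse_fraction, config$standard_relapse_fraction
  )
  dplyr::bind_rows(initial, relapse)
}

#' Run the full estimation pipeline
#'
#' Cohorts, medicine need, budget and (when sales data are configured) the
#' sales sufficiency comparison, for one population scope. Need comes from
#' the treatment protocols unless the configuration names a `needs` file,
#' in which case the file's unit totals feed the budget and comparison paths
#' directly; with a needs file, `bound` scales units by the ratio of the
#' scoped bound total to the scoped point total (need is linear in cohort
#' counts under fixed stratification fractions).
#'
#' @inheritParams build_cohorts
#' @return A list of class `all_estimate` with elements `cohorts`, `needs`,
#'   `budget`, `comparison` (or `NULL`), `scope`, `year`.
#' @export
run_estimation <- function(config, scope = config$scope,
                           bound = c("point", "lower", "upper")) {
  bound <- match.arg(bound)
  scope <- normalize_scope(scope)
  cohorts <- build_cohorts(config, scope, bound)
  if (is.null(config$needs)) {
    needs <- aggregate_need(cohorts, config$protocols, config$anthropometry,
                            unit_policy = config$unit_policy)
  } else {
    needs <- config$needs[config$needs$scope == scope, , drop = FALSE]
    if (nrow(needs) == 0) {
      stop_config(sprintf("needs file has no rows for scope '%s'", scope))
    }
    if (bound != "point") {
      scoped <- scope_population(config$incidence, scope, config$year)
      ref <- sum(scoped$count)
      chosen <- sum(if (bound == "lower") scoped$count_lb else scoped$count_ub)
      f <- chosen / ref
      for (col in c("total_amount", "total_lb", "total_ub",
                    "smallest_units", "units_lb", "units_ub")) {
        needs[[col]] <- needs[[col]] * f
      }
    }
  }
  budget <- expenditure(needs, config$prices, config$protocols,
                        health_expenditure_usd = config$health_expenditure_usd)
  comparison <- NULL
  if (!is.null(config$sales)) {
    comparison <- compare_sales_to_need(
      needs, config$sales, config$protocols, config$year
    )
  }
  structure(
    list(cohorts = cohorts, needs = needs, budget = budget,
         comparison = comparison, scope = scope, year = config$year),
    class = "all_estimate"
  )
}

#' @export
print.all_estimate <- function(x, ...) {
  cat(sprintf("<all_estimate> year %d, scope %s\n", x$year, x$scope))
  counts <- report_counts(x$cohorts)
  by_arm <- tapply(counts$count, counts$arm, sum)
  cat("  cohort counts (display-rounded):",
      paste(sprintf("%s=%d", names(by_arm), as.integer(by_arm)), collapse = ", "),
      "\n")
  cat(sprintf("  total budget: US$ %s",
              format(round_half_away(x$budget$total), big.mark = " ")))
  if (!is.null(x$budget$health_expenditure_share_pct)) {
    cat(sprintf(" (%.3f%% of health expenditure)",
                x$budget$health_expenditure_share_pct))
  }
  cat("\n")
  if (!is.null(x$comparison)) {
    for (k in seq_len(nrow(x$comparison))) {
      cat(sprintf("  sufficiency %s: %.1f\n",
                  x$comparison$inn[k], x$comparison$ratio_reported[k]))
    }
  }
  invisible(x)
}

#' Deterministic sensitivity scenarios
#'
#' Re-runs the pipeline under named parameter overrides and tabulates totals,
#' health-expenditure shares and deltas against the base run. Supported
#' overrides per scenario: `scope`, `relapse_fraction`,
#' `standard_relapse_fraction`, `incidence_bound` (`point`/`lower`/`upper`)
#' and `wastage_fraction`.
#'
#' With protocol-derived needs every scenario is a full pipeline recompute.
#' With a needs file, relapse overrides scale expenditure by the ratio of
#' course-equivalents `(1 + relapse_fraction)` — i.e. a relapse course is
#' costed like an initial course, the only allocation the file's aggregate
#' totals support.
#'
#' @param config A `run_config`.
#' @param scenarios Named list of scenario override lists.
#' @return A tibble with one row per scenario (plus the base run): `scenario`,
#'   `scope`, `total_usd`, `wastage_usd`, `total_with_wastage_usd`,
#'   `health_share_pct`, `delta_usd`.
#' @export
run_scenarios <- function(config, scenarios) {
  if (is.null(names(scenarios)) || any(names(scenarios) == "")) {
    stop_usage("scenarios must be a named list")
  }
  base <- run_estimation(config)
  one_row <- function(name, scope, total, wastage) {
    tibble::tibble(
      scenario = name,
      scope = scope,
      total_usd = total,
      wastage_usd = wastage,
      total_with_wastage_usd = total + wastage,
      health_share_pct = health_expenditure_share(
        total + wastage, config$health_expenditure_usd
      ),
      delta_usd = total + wastage - base$budget$total
    )
  }
  rows <- list(one_row("base", base$scope, base$budget$total, 0))
  for (name in names(scenarios)) {
    sc <- scenarios[[name]]
    row <- tryCatch({
      for (key in c("relapse_fraction", "standard_relapse_fraction",
                    "wastage_fraction")) {
        val <- sc[[key]]
        if (!is.null(val) && (val < 0 || val > 1)) {
          stop_validation(sprintf("%s outside [0, 1]", key))
        }
      }
      cfg <- config
      cfg$scope <- normalize_scope(sc$scope %||% config$scope)
      cfg$relapse_fraction <- sc$relapse_fraction %||% config$relapse_fraction
      cfg$standard_relapse_fraction <-
        sc$standard_relapse_fraction %||% config$standard_relapse_fraction
      bound <- sc$incidence_bound %||% "point"
      est <- run_estimation(cfg, bound = bound)
      total <- est$budget$total
      parenteral <- sum(est$budget$items$cost_usd[est$budget$items$parenteral])
      if (!is.null(config$needs)) {
        # file-derived needs cannot see a relapse override; scale by the
        # change in course-equivalents
        f <- (1 + cfg$relapse_fraction) / (1 + config$relapse_fraction)
        total <- total * f
        parenteral <- parenteral * f
      }
      wastage <- (sc$wastage_fraction %||% 0) * parenteral
      one_row(name, cfg$scope, total, wastage)
    }, allquant_error = function(e) {
      stop_usage(sprintf("scenario '%s': %s", name, conditionMessage(e)))
    })
    rows[[length(rows) + 1L]] <- row
  }
  dplyr::bind_rows(rows)
}
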