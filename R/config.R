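#' Load and validate a run configuration
#'
#' A run configuration is a YAML file that names every input file and every
#' model parameter of an estimation run. All referenced files are read and
#' cross-validated up front — age bands must be covered by the anthropometric
#' reference and the risk rules, the protocol set must validate strictly —
#' so that no computation starts on a broken input set.
#'
#' Keys:
#' * `year`: calendar year of the run.
#' * `scope`: default population scope (`diagnosed` or
#'   `diagnosed_plus_undiagnosed` / `dx+udx`).
#' * `files`: paths (relative to the config file) for `incidence`,
#'   `anthropometry`, `protocols`, `prices`, and optionally `sales` and
#'   `needs`. When a `needs` file is present the budget and comparison paths
#'   use it instead of protocol-derived estimates (the case when published
#'   unit totals are available but dose schedules are not).
#' * `risk_rules`: list of `{age_band, standard_fraction}`.
#' * `relapse`: either `relapse_fraction` or `relapse_count` (a count of
#'   relapsing diagnosed children, divided by the diagnosed-scope total of
#'   the run year to obtain the fraction), plus `standard_relapse_fraction`.
#' * `health_expenditure_usd`: national health expenditure (US$).
#' * `wastage_fractions`: optional list of vial-wastage fractions to test.
#' * `unit_policy`: optional, `aggregate` (default) or `per_patient`.
#'
#' @param path Path to the YAML configuration.
#' @return A `run_config` object: the parsed parameters plus every input
#'   loaded as a tibble (or `protocol_set`).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: '%s'", path))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_config(sprintf("could not parse config '%s': %s", path, conditionMessage(e)))
  })
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base_dir, p) else p
  }
  for (key in c("year", "scope", "files", "risk_rules", "relapse",
                "health_expenditure_usd")) {
    if (is.null(raw[[key]])) {
      stop_config(sprintf("config '%s' lacks required key '%s'", path, key))
    }
  }
  for (key in c("incidence", "anthropometry", "protocols", "prices")) {
    if (is.null(raw$files[[key]])) {
      stop_config(sprintf("config '%s' lacks files.%s", path, key))
    }
  }
  scope <- normalize_scope(raw$scope)
  year <- as.integer(raw$year)

  incidence <- read_incidence(resolve(raw$files$incidence))
  if (!any(incidence$year == year)) {
    stop_config(sprintf("incidence file has no rows for configured year %d", year))
  }
  anthropometry <- read_anthropometry(resolve(raw$files$anthropometry))
  protocols <- read_protocols(resolve(raw$files$protocols))
  validate_protocol_set(protocols, strict = TRUE)
  prices <- read_prices(resolve(raw$files$prices))
  sales <- if (!is.null(raw$files$sales)) read_sales(resolve(raw$files$sales))
  needs <- if (!is.null(raw$files$needs)) read_needs(resolve(raw$files$needs))

  risk_rules <- dplyr::bind_rows(lapply(raw$risk_rules, function(r) {
    tibble::tibble(
      age_band = as.character(require_field(r, "age_band", path, "risk rule")),
      standard_fraction = as.numeric(
        require_field(r, "standard_fraction", path, "risk rule")
      )
    )
  }))
  if (any(risk_rules$standard_fraction < 0 | risk_rules$standard_fraction > 1)) {
    stop_config(sprintf("config '%s': standard_fraction outside [0, 1]", path))
  }
  bands <- unique(incidence$age_band[incidence$year == year])
  uncovered <- setdiff(bands, risk_rules$age_band)
  if (length(uncovered)) {
    stop_config(sprintf(
      "config '%s': no risk rule for age band(s) %s",
      path, paste(uncovered, collapse = ", ")
    ))
  }
  no_anthro <- setdiff(bands, anthropometry$age_band)
  if (length(no_anthro)) {
    stop_config(sprintf(
      "config '%s': no anthropometric reference for age band(s) %s",
      path, paste(no_anthro, collapse = ", ")
    ))
  }

  rel <- raw$relapse
  srf <- as.numeric(require_field(rel, "standard_relapse_fraction", path, "relapse"))
  if (!is.null(rel$relapse_fraction) && !is.null(rel$relapse_count)) {
    stop_config(sprintf(
      "config '%s': give either relapse.relapse_fraction or relapse.relapse_count",
      path
    ))
  }
  rf <- if (!is.null(rel$relapse_count)) {
    dx_total <- sum(incidence$diagnosed[incidence$year == year])
    if (dx_total <= 0) stop_config("relapse_count given but diagnosed total is zero")
    as.numeric(rel$relapse_count) / dx_total
  } else if (!is.null(rel$relapse_fraction)) {
    as.numeric(rel$relapse_fraction)
  } else {
    stop_config(sprintf("config '%s': relapse block lacks a fraction or count", path))
  }
  if (rf < 0 || rf > 1) {
    stop_config(sprintf("config '%s': relapse fraction %.3f outside [0, 1]", path, rf))
  }
  if (srf < 0 || srf > 1) {
    stop_config(sprintf("config '%s': standard_relapse_fraction outside [0, 1]", path))
  }

  he <- as.numeric(raw$health_expenditure_usd)
  if (!is.finite(he) || he <= 0) {
    stop_config(sprintf("config '%s': health_expenditure_usd must be positive", path))
  }
  wf <- as.numeric(raw$wastage_fractions %||% numeric())
  if (any(wf < 0 | wf > 1)) {
    stop_config(sprintf("config '%s': wastage_fractions outside [0, 1]", path))
  }
  unit_policy <- raw$unit_policy %||% "aggregate"
  if (!unit_policy %in% c("aggregate", "per_patient")) {
    stop_config(sprintf("config '%s': unknown unit_policy '%s'", path, unit_policy))
  }

  structure(list(
    path = normalizePath(path),
    year = year,
    scope = scope,
    incidence = incidence,
    anthropometry = anthropometry,
    protocols = protocols,
    prices = prices,
    sales = sales,
    needs = needs,
    risk_rules = risk_rules,
    relapse_fraction = rf,
    standard_relapse_fraction = srf,
    health_expenditure_usd = he,
    wastage_fractions = wf,
    unit_policy = unit_policy
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  year: %d, scope: %s\n", x$year, x$scope))
  cat(sprintf("  age bands: %s\n", paste(unique(x$incidence$age_band), collapse = ", ")))
  cat(sprintf("  relapse fraction: %.4f (standard split %.2f)\n",
              x$relapse_fraction, x$standard_relapse_fraction))
  cat(sprintf("  health expenditure: US$ %s\n",
              format(x$health_expenditure_usd, big.mark = " ", scientific = FALSE)))
  cat(sprintf("  needs source: %s\n",
              if (is.null(x$needs)) "treatment protocols" else "needs file"))
  invisible(x)
}
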