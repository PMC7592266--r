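# Seeded synthetic-data generator: a reproducible full input bundle whose
# ground truth is known by construction, used as the test surface for every
# module. It emulates the structure of real inputs (age-banded incidence with
# uncertainty bounds, a four-arm protocol set, prices, pack-level sales), not
# any particular country's data.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic input bundle
#'
#' Builds a complete, internally consistent input set: incidence with
#' `lb <= n <= ub`, an anthropometric reference, a four-arm protocol set over
#' `n_medicines` formulations, prices, and sales records constructed as
#' `sales_multiplier` times the estimated need — so the true sufficiency
#' ratio is known by construction. The same seed always yields an identical
#' bundle.
#'
#' @param seed Integer seed governing all randomness.
#' @param n_medicines Number of medicines (`>= 1`).
#' @param n_bands Number of five-year age bands (`>= 1`).
#' @param scale Multiplier applied to all incidence counts; pipeline totals
#'   are linear in it.
#' @param sales_multiplier Sales volumes are this multiple of estimated need.
#' @param scope Population scope used when constructing the sales records.
#' @param year Calendar year stamped on the inputs.
#' @param include_per_kg If `TRUE`, some dose rules use the `per_kg` basis;
#'   the default mirrors common practice of BSA-based and fixed dosing.
#' @return A `synthetic_bundle`: list with `incidence`, `anthropometry`,
#'   `protocols`, `prices`, `sales`, `risk_rules`, relapse parameters,
#'   `health_expenditure_usd`, `year`, `scope`, `seed`, and `expected`
#'   (the need table the sales were built from, plus the true ratio).
#' @export
generate_synthetic_inputs <- function(seed, n_medicines = 6, n_bands = 3,
                                      scale = 1, sales_multiplier = 2,
                                      scope = "diagnosed", year = 2020,
                                      include_per_kg = FALSE) {
  if (n_medicines < 1 || n_bands < 1) {
    stop_usage("n_medicines and n_bands must be >= 1")
  }
  scope <- normalize_scope(scope)
  with_seed(seed, {
    bands <- paste0(5 * (seq_len(n_bands) - 1), "-", 5 * seq_len(n_bands) - 1)

    dx <- scale * stats::runif(n_bands, 50, 200)
    udx <- scale * stats::runif(n_bands, 10, 100)
    incidence <- tibble::tibble(
      year = year,
      age_band = bands,
      diagnosed = dx,
      diagnosed_lb = dx * stats::runif(n_bands, 0.6, 0.9),
      diagnosed_ub = dx * stats::runif(n_bands, 1.1, 1.5),
      undiagnosed = udx,
      undiagnosed_lb = udx * stats::runif(n_bands, 0.6, 0.9),
      undiagnosed_ub = udx * stats::runif(n_bands, 1.1, 1.5)
    )

    anthropometry <- tibble::tibble(
      age_band = bands,
      mean_height_cm = 80 + 18 * (seq_len(n_bands) - 1) +
        round(stats::runif(n_bands, -3, 3), 1),
      mean_weight_kg = 12 + 8 * (seq_len(n_bands) - 1) +
        round(stats::runif(n_bands, -1, 1), 1)
    )

    inns <- sprintf("synmed%02d", seq_len(n_medicines))
    n_chemo <- if (n_medicines >= 4) floor(n_medicines / 4) else
      as.integer(n_medicines >= 2)
    classes <- c(
      rep("antineoplastic", n_medicines - n_chemo),
      rep("chemoprotective", n_chemo)
    )
    medicines <- tibble::tibble(inn = inns, drug_class = classes)
    routes <- c("intravenous", "oral", "intramuscular", "intrathecal")
    formulations <- tibble::tibble(
      inn = inns,
      route = routes[(seq_len(n_medicines) - 1) %% 4 + 1],
      smallest_unit_strength = sample(c(1, 2.5, 5, 10, 50, 100),
                                      n_medicines, replace = TRUE),
      unit_kind = "mg",
      predominantly_paediatric_all = seq_len(n_medicines) <= min(2, n_medicines)
    )

    bases <- c("per_m2", "fixed", if (include_per_kg) "per_kg")
    base_prob <- c(0.6, 0.25, if (include_per_kg) 0.15)
    rules <- dplyr::bind_rows(lapply(protocol_arms, function(arm) {
      tibble::tibble(
        arm = arm,
        inn = inns,
        route = formulations$route,
        dose_basis = sample(bases, n_medicines, replace = TRUE, prob = base_prob),
        dose_amount = round(stats::runif(n_medicines, 5, 100), 1),
        n_administrations = sample(1:12, n_medicines, replace = TRUE),
        age_bands = rep(list(NULL), n_medicines),
        phase = NA_character_
      )
    }))
    protocols <- new_protocol_set(medicines, formulations, rules)

    prices <- tibble::tibble(
      inn = inns,
      route = formulations$route,
      smallest_unit_strength = formulations$smallest_unit_strength,
      unit_price_usd = round(stats::runif(n_medicines, 0.5, 50), 2),
      price_year = year,
      formulation = formulation_label(inns, formulations$route)
    )

    risk_rules <- tibble::tibble(
      age_band = bands,
      standard_fraction = round(stats::runif(n_bands, 0, 1), 2)
    )
    relapse_fraction <- 0.22
    standard_relapse_fraction <- 0.28

    scoped <- scope_population(incidence, scope, year)
    initial <- stratify_risk(scoped, risk_rules)
    cohorts <- dplyr::bind_rows(
      initial,
      apply_relapse(initial, relapse_fraction, standard_relapse_fraction)
    )
    needs <- aggregate_need(cohorts, protocols, anthropometry)

    packs <- round(needs$smallest_units * sales_multiplier)
    sales <- tibble::tibble(
      inn = needs$inn,
      route = needs$route,
      strength = formulations$smallest_unit_strength[
        match(needs$inn, formulations$inn)],
      strength_unit = "mg",
      units_per_pack = 1,
      packs_sold = packs,
      quarter = paste0(year, "-Q1"),
      year = year
    )

    structure(list(
      incidence = incidence,
      anthropometry = anthropometry,
      protocols = protocols,
      prices = prices,
      sales = sales,
      risk_rules = risk_rules,
      relapse_fraction = relapse_fraction,
      standard_relapse_fraction = standard_relapse_fraction,
      health_expenditure_usd = 1e9,
      year = year,
      scope = scope,
      seed = seed,
      expected = list(
        needs = needs,
        sufficiency_ratio = ifelse(
          needs$smallest_units > 0, packs / needs$smallest_units, NA_real_
        )
      )
    ), class = "synthetic_bundle")
  })
}

#' Write a synthetic bundle to a directory
#'
#' Writes `incidence.csv`, `anthropometry.csv`, `protocols.yaml`,
#' `prices.csv`, `sales.csv` and a `config.yaml` tying them together, so the
#' bundle round-trips through [load_run_config()].
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Target directory (created if absent).
#' @return The path of the written `config.yaml`, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name, drop = character()) {
    df <- as.data.frame(df)[setdiff(names(df), drop)]
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(bundle$incidence, "incidence.csv")
  w(bundle$anthropometry, "anthropometry.csv")
  w(bundle$prices, "prices.csv", drop = "formulation")
  w(bundle$sales, "sales.csv", drop = "year")
  write_protocols(bundle$protocols, file.path(dir, "protocols.yaml"))
  config <- list(
    year = bundle$year,
    scope = bundle$scope,
    files = list(
      incidence = "incidence.csv",
      anthropometry = "anthropometry.csv",
      protocols = "protocols.yaml",
      prices = "prices.csv",
      sales = "sales.csv"
    ),
    risk_rules = lapply(seq_len(nrow(bundle$risk_rules)), function(i) {
      list(age_band = bundle$risk_rules$age_band[i],
           standard_fraction = bundle$risk_rules$standard_fraction[i])
    }),
    relapse = list(
      relapse_fraction = bundle$relapse_fraction,
      standard_relapse_fraction = bundle$standard_relapse_fraction
    ),
    health_expenditure_usd = bundle$health_expenditure_usd,
    wastage_fractions = c(0.2, 0.4),
    unit_policy = "aggregate"
  )
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}
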