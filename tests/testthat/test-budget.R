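one_med_setup <- function(units = 100, price = 2, route = "intravenous") {
  p <- simple_protocols()
  needs <- tibble::tibble(
    formulation = "drugx:intravenous", inn = "drugx", route = route,
    unit_kind = "mg", scope = "diagnosed",
    total_amount = units * 50, total_lb = units * 50, total_ub = units * 50,
    smallest_units = units, units_lb = units, units_ub = units
  )
  prices <- tibble::tibble(
    inn = "drugx", route = "intravenous", smallest_unit_strength = 50,
    unit_price_usd = price, price_year = 2017,
    formulation = "drugx:intravenous"
  )
  list(p = p, needs = needs, prices = prices)
}

test_that("expenditure is units times unit price with full shares", {
  s <- one_med_setup(units = 100, price = 2)
  rep <- expenditure(s$needs, s$prices, s$p)
  expect_equal(rep$total, 200)
  expect_equal(rep$items$share_pct, 100)
  expect_equal(rep$subtotal_antineoplastic, 200)
  expect_equal(rep$subtotal_chemoprotective, 0)

  missing <- s$prices[0, ]
  expect_error(expenditure(s$needs, missing, s$p), "drugx",
               class = "allquant_data_error")
})

test_that("budget report is additive and its shares sum to 100", {
  b <- generate_synthetic_inputs(seed = 52, n_medicines = 8)
  est <- {
    scoped <- scope_population(b$incidence, "diagnosed", b$year)
    initial <- stratify_risk(scoped, b$risk_rules)
    cohorts <- dplyr::bind_rows(
      initial,
      apply_relapse(initial, b$relapse_fraction, b$standard_relapse_fraction)
    )
    needs <- aggregate_need(cohorts, b$protocols, b$anthropometry)
    expenditure(needs, b$prices, b$protocols)
  }
  expect_equal(est$subtotal_antineoplastic + est$subtotal_chemoprotective,
               est$total, tolerance = 1e-9)
  expect_equal(sum(est$items$cost_usd), est$total, tolerance = 1e-9)
  expect_equal(sum(est$items$share_pct), 100, tolerance = 1e-9)
  expect_true(all(est$items$cost_lb <= est$items$cost_usd + 1e-9 &
                    est$items$cost_usd <= est$items$cost_ub + 1e-9))
})

test_that("price homogeneity: scaling all prices scales the total, not the shares", {
  b <- generate_synthetic_inputs(seed = 53, n_medicines = 6)
  scoped <- scope_population(b$incidence, "diagnosed", b$year)
  cohorts <- stratify_risk(scoped, b$risk_rules)
  needs <- aggregate_need(cohorts, b$protocols, b$anthropometry)
  base <- expenditure(needs, b$prices, b$protocols)
  prices_k <- b$prices
  prices_k$unit_price_usd <- prices_k$unit_price_usd * 3
  scaled <- expenditure(needs, prices_k, b$protocols)
  expect_equal(scaled$total, base$total * 3, tolerance = 1e-12)
  expect_equal(scaled$items$share_pct, base$items$share_pct, tolerance = 1e-9)
})

test_that("health expenditure share is a percentage with a guarded denominator", {
  expect_equal(health_expenditure_share(814952, 17055e6),
               100 * 814952 / 17055e6)
  expect_equal(round(health_expenditure_share(814952, 17055e6), 3), 0.005)
  expect_equal(round(health_expenditure_share(1365422, 17055e6), 3), 0.008)
  expect_equal(health_expenditure_share(0, 17055e6), 0)
  expect_error(health_expenditure_share(100, 0), class = "allquant_domain_error")
})

test_that("vial wastage is linear and touches only parenteral spend", {
  s <- one_med_setup(units = 100, price = 2)
  rep <- expenditure(s$needs, s$prices, s$p)
  expect_equal(vial_wastage_cost(rep, 0), 0)
  expect_equal(vial_wastage_cost(rep, 0.2), 40)
  expect_equal(vial_wastage_cost(rep, 0.4), 2 * vial_wastage_cost(rep, 0.2))
  set.seed(54)
  for (f in runif(5)) {
    expect_equal(vial_wastage_cost(rep, f),
                 f / 0.2 * vial_wastage_cost(rep, 0.2), tolerance = 1e-12)
  }
  expect_error(vial_wastage_cost(rep, 1.2), class = "allquant_validation_error")

  # an all-oral formulary wastes nothing
  oral <- protoset(
    list(med("drugx")),
    list(form("drugx", route = "oral")),
    arms = {
      r <- list(rule("drugx", route = "oral"))
      list(standard = r, high = r, relapse_standard = r, relapse_high = r)
    }
  )
  needs_oral <- s$needs
  needs_oral$formulation <- "drugx:oral"
  needs_oral$route <- "oral"
  prices_oral <- s$prices
  prices_oral$route <- "oral"
  prices_oral$formulation <- "drugx:oral"
  rep_oral <- expenditure(needs_oral, prices_oral, oral)
  expect_equal(vial_wastage_cost(rep_oral, 0.4), 0)
})

test_that("price inflation compounds annually", {
  prices <- tibble::tibble(
    inn = "drugx", route = "oral", smallest_unit_strength = 50,
    unit_price_usd = 100, price_year = 2017, formulation = "drugx:oral"
  )
  expect_equal(inflate_prices(prices, 0, 2017, 2021)$unit_price_usd, 100)
  expect_equal(inflate_prices(prices, 0.03, 2017, 2019)$unit_price_usd, 106.09)
  expect_equal(inflate_prices(prices, -0.5, 2017, 2018)$unit_price_usd, 50)
  expect_equal(inflate_prices(prices, 0.03, 2017, 2021)$price_year, 2021)
  expect_error(inflate_prices(prices, 0.03, 2021, 2017),
               class = "allquant_usage_error")
  expect_error(inflate_prices(prices, -1.5, 2017, 2018),
               class = "allquant_validation_error")
})

test_that("scenario runs reproduce the base case and respect monotonicity", {
  b <- generate_synthetic_inputs(seed = 55, n_medicines = 6)
  dir <- tempfile()
  cfg <- load_run_config(write_synthetic_bundle(b, dir))
  out <- run_scenarios(cfg, list(
    same = list(),
    upper = list(incidence_bound = "upper"),
    more_relapse = list(relapse_fraction = 0.5),
    wasteful = list(wastage_fraction = 0.2)
  ))
  base <- out$total_usd[out$scenario == "base"]
  expect_equal(out$total_usd[out$scenario == "same"], base)
  expect_equal(out$delta_usd[out$scenario == "same"], 0)
  expect_gte(out$total_usd[out$scenario == "upper"], base)
  expect_gte(out$total_usd[out$scenario == "more_relapse"], base)

  est <- run_estimation(cfg)
  expect_equal(
    out$total_with_wastage_usd[out$scenario == "wasteful"],
    est$budget$total + vial_wastage_cost(est$budget, 0.2),
    tolerance = 1e-9
  )
  expect_error(run_scenarios(cfg, list(list())), class = "allquant_usage_error")
  expect_error(
    run_scenarios(cfg, list(bad = list(relapse_fraction = 2))),
    class = "allquant_usage_error"
  )
})

test_that("case-study pessimistic scenarios stay below 0.02% of health expenditure", {
  cfg <- thai_config()
  out <- run_scenarios(cfg, list(
    pessimistic = list(scope = "dx+udx", incidence_bound = "upper",
                       relapse_fraction = 0.5)
  ))
  share <- out$health_share_pct[out$scenario == "pessimistic"]
  expect_gt(share, out$health_share_pct[out$scenario == "base"])
  expect_lt(share, 0.02)
})
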