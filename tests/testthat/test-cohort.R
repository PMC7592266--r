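test_that("scope selection adds undiagnosed counts component-wise", {
  inc <- tiny_incidence(diagnosed = 146, undiagnosed = 99, bands = "0-4")
  expect_equal(scope_population(inc, "diagnosed")$count, 146)
  expect_equal(scope_population(inc, "combined")$count, 245)
  expect_equal(scope_population(inc, "dx+udx")$count, 245)

  inc0 <- tiny_incidence(diagnosed = c(10, 20), undiagnosed = c(0, 0))
  expect_equal(scope_population(inc0, "diagnosed_plus_undiagnosed")$count,
               scope_population(inc0, "diagnosed")$count)

  expect_error(scope_population(inc, "everyone"), class = "allquant_config_error")
})

test_that("incidence reader validates bound ordering and schema", {
  path <- tempfile(fileext = ".csv")
  bad <- data.frame(
    year = 2017, age_band = "0-4",
    diagnosed = 100, diagnosed_lb = 120, diagnosed_ub = 150,
    undiagnosed = 10, undiagnosed_lb = 5, undiagnosed_ub = 20
  )
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_incidence(path), "bound ordering", class = "allquant_data_error")

  good <- bad
  good$diagnosed_lb <- 80
  write.csv(good, path, row.names = FALSE)
  expect_equal(read_incidence(path)$diagnosed, 100)
})

test_that("risk stratification splits counts by the band's standard fraction", {
  rules <- tibble::tibble(age_band = c("0-4", "10-14"),
                          standard_fraction = c(0.65, 0))
  scoped <- tibble::tibble(
    age_band = c("0-4", "10-14"), scope = "diagnosed",
    count = c(100, 68), count_lb = c(60, 41), count_ub = c(130, 94)
  )
  out <- stratify_risk(scoped, rules)
  get <- function(band, arm) out$count[out$age_band == band & out$arm == arm]
  expect_equal(get("0-4", "standard"), 65)
  expect_equal(get("0-4", "high"), 35)
  expect_equal(get("10-14", "standard"), 0)
  expect_equal(get("10-14", "high"), 68)

  all_std <- stratify_risk(scoped, tibble::tibble(
    age_band = c("0-4", "10-14"), standard_fraction = c(1, 1)
  ))
  expect_equal(sum(all_std$count[all_std$arm == "high"]), 0)

  expect_error(
    stratify_risk(scoped, rules[1, ]),
    "10-14", class = "allquant_config_error"
  )
  expect_error(
    stratify_risk(scoped, tibble::tibble(age_band = c("0-4", "10-14"),
                                         standard_fraction = c(1.2, 0))),
    class = "allquant_validation_error"
  )
})

test_that("stratification conserves counts, bounds and scales linearly", {
  set.seed(21)
  for (i in 1:10) {
    n_bands <- sample(2:5, 1)
    bands <- paste0("b", seq_len(n_bands))
    scoped <- tibble::tibble(
      age_band = bands, scope = "diagnosed",
      count = runif(n_bands, 10, 200)
    )
    scoped$count_lb <- scoped$count * runif(n_bands, 0.5, 1)
    scoped$count_ub <- scoped$count * runif(n_bands, 1, 1.8)
    rules <- tibble::tibble(age_band = bands,
                            standard_fraction = runif(n_bands))
    out <- stratify_risk(scoped, rules)
    per_band <- tapply(out$count, out$age_band, sum)
    expect_equal(as.numeric(per_band[scoped$age_band]), scoped$count,
                 tolerance = 1e-12)
    expect_true(all(out$count_lb <= out$count + 1e-12 &
                      out$count <= out$count_ub + 1e-12))
    k <- runif(1, 0.5, 3)
    scaled <- scoped
    scaled$count <- scoped$count * k
    scaled$count_lb <- scoped$count_lb * k
    scaled$count_ub <- scoped$count_ub * k
    expect_equal(stratify_risk(scaled, rules)$count, out$count * k)
  }
})

test_that("the relapse cascade re-assesses risk independently of the initial arm", {
  scoped <- tibble::tibble(
    age_band = "0-14", scope = "diagnosed",
    count = 69 / 0.22, count_lb = 69 / 0.22, count_ub = 69 / 0.22
  )
  initial <- stratify_risk(
    scoped, tibble::tibble(age_band = "0-14", standard_fraction = 0.65)
  )
  rel <- apply_relapse(initial, 0.22, 0.28)
  std <- sum(rel$count[rel$arm == "relapse_standard"])
  high <- sum(rel$count[rel$arm == "relapse_high"])
  expect_equal(std, 19.32, tolerance = 1e-9)
  expect_equal(high, 49.68, tolerance = 1e-9)
  shown <- report_counts(rel)
  expect_equal(sum(shown$count[shown$arm == "relapse_standard"]), 19)
  expect_equal(sum(shown$count[shown$arm == "relapse_high"]), 50)

  expect_equal(nrow(apply_relapse(initial, 0, 0.28)), 0)

  half <- apply_relapse(initial, 0.4, 0.5)
  expect_equal(sum(half$count[half$arm == "relapse_standard"]),
               sum(half$count[half$arm == "relapse_high"]))

  mixed <- dplyr::bind_rows(
    initial, dplyr::mutate(initial, scope = "diagnosed_plus_undiagnosed")
  )
  expect_error(apply_relapse(mixed, 0.22, 0.28), class = "allquant_usage_error")
  expect_error(apply_relapse(rel, 0.22, 0.28), class = "allquant_usage_error")
  expect_error(apply_relapse(initial, 1.5, 0.28),
               class = "allquant_validation_error")
})

test_that("relapse totals and bounds scale proportionally with the pool", {
  set.seed(22)
  for (i in 1:8) {
    bands <- paste0("b", 1:3)
    scoped <- tibble::tibble(
      age_band = bands, scope = "diagnosed", count = runif(3, 20, 300)
    )
    scoped$count_lb <- scoped$count * 0.7
    scoped$count_ub <- scoped$count * 1.4
    initial <- stratify_risk(
      scoped, tibble::tibble(age_band = bands, standard_fraction = runif(3))
    )
    rf <- runif(1, 0.05, 0.6)
    rel <- apply_relapse(initial, rf, runif(1))
    expect_equal(sum(rel$count), rf * sum(initial$count), tolerance = 1e-12)
    expect_equal(sum(rel$count_ub), rf * sum(initial$count_ub), tolerance = 1e-12)
    expect_true(all(rel$count_lb <= rel$count & rel$count <= rel$count_ub))
  }
})

test_that("display rounding is half away from zero and leaves internals alone", {
  x <- cohort_row("0-4", "standard", 2.5)
  x <- dplyr::bind_rows(x, cohort_row("0-4", "high", -2.5),
                        cohort_row("5-9", "standard", 49.68),
                        cohort_row("5-9", "high", 19.32))
  out <- report_counts(x)
  expect_equal(out$count, c(3, -3, 50, 19))
  expect_equal(x$count, c(2.5, -2.5, 49.68, 19.32))  # input untouched
})
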