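# Builders for small in-code fixtures, and an independent per-child oracle.

# Write a protocol set defined as R lists to YAML and load it through the
# public reader, so tests exercise the same path users do.
protoset <- function(medicines, formulations, arms) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(
    list(formulary = list(medicines = medicines, formulations = formulations),
         arms = arms),
    path
  )
  read_protocols(path)
}

med <- function(inn, drug_class = "antineoplastic") {
  list(inn = inn, drug_class = drug_class)
}

form <- function(inn, route = "intravenous", strength = 50, unit_kind = "mg",
                 paed = FALSE) {
  out <- list(inn = inn, route = route, smallest_unit_strength = strength,
              unit_kind = unit_kind)
  if (paed) out$predominantly_paediatric_all <- TRUE
  out
}

rule <- function(inn, route = "intravenous", basis = "per_m2", amount = 100,
                 n = 1, age_bands = NULL) {
  out <- list(inn = inn, route = route, dose_basis = basis,
              dose_amount = amount, n_administrations = n)
  if (!is.null(age_bands)) out$age_bands <- as.list(age_bands)
  out
}

# One medicine, all four arms carrying the same single rule.
simple_protocols <- function(amount = 100, n = 1, basis = "per_m2",
                             strength = 50) {
  r <- list(rule("drugx", basis = basis, amount = amount, n = n))
  protoset(
    medicines = list(med("drugx")),
    formulations = list(form("drugx", strength = strength)),
    arms = list(standard = r, high = r, relapse_standard = r, relapse_high = r)
  )
}

simple_anthropometry <- function(bands = c("0-4", "5-9", "10-14"),
                                 heights = c(100, 125, 150),
                                 weights = c(36, 25, 42)) {
  tibble::tibble(
    age_band = bands,
    mean_height_cm = heights[seq_along(bands)],
    mean_weight_kg = weights[seq_along(bands)]
  )
}

cohort_row <- function(age_band, arm, count, scope = "diagnosed",
                       lb = count, ub = count) {
  tibble::tibble(age_band = age_band, arm = arm, scope = scope,
                 count = count, count_lb = lb, count_ub = ub)
}

tiny_incidence <- function(diagnosed, undiagnosed,
                           bands = paste0(seq_along(diagnosed)), year = 2017) {
  tibble::tibble(
    year = year, age_band = bands,
    diagnosed = diagnosed, diagnosed_lb = diagnosed, diagnosed_ub = diagnosed,
    undiagnosed = undiagnosed, undiagnosed_lb = undiagnosed,
    undiagnosed_ub = undiagnosed
  )
}

# Independent brute-force oracle: iterate integer-count cohorts child by
# child and accumulate dose_amount * basis factor * n_administrations per
# formulation straight from the rules table, without calling the package's
# aggregation path.
brute_force_need <- function(cohorts, protocols, anthropometry) {
  totals <- numeric(0)
  for (k in seq_len(nrow(cohorts))) {
    n_children <- cohorts$count[k]
    stopifnot(n_children == floor(n_children))
    band <- cohorts$age_band[k]
    i <- match(band, anthropometry$age_band)
    bsa <- sqrt(anthropometry$mean_height_cm[i] *
                  anthropometry$mean_weight_kg[i] / 3600)
    wt <- anthropometry$mean_weight_kg[i]
    for (child in seq_len(n_children)) {
      rr <- protocols$rules[protocols$rules$arm == cohorts$arm[k], ]
      for (j in seq_len(nrow(rr))) {
        bands_j <- rr$age_bands[[j]]
        if (!is.null(bands_j) && !(band %in% bands_j)) next
        fac <- switch(rr$dose_basis[j], per_m2 = bsa, per_kg = wt, fixed = 1)
        f <- rr$formulation[j]
        totals[f] <- (if (f %in% names(totals)) totals[[f]] else 0) +
          rr$dose_amount[j] * fac * rr$n_administrations[j]
      }
    }
  }
  totals
}

thai_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- load_run_config(thai_fixture_path("config.yaml"))
    }
    cache
  }
})
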