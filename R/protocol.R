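#' Read a declarative protocol set
#'
#' A protocol set is a YAML file with two top-level keys:
#'
#' * `formulary`: `medicines` (a list of `inn` + `drug_class`, where
#'   `drug_class` is `antineoplastic` or `chemoprotective`) and `formulations`
#'   (each with `inn`, `route`, `smallest_unit_strength`, `unit_kind` (`mg` or
#'   `active_units`) and optionally `predominantly_paediatric_all: true` for
#'   medicines whose market volume is attributable mainly to paediatric ALL).
#' * `arms`: one entry per protocol arm (`standard`, `high`,
#'   `relapse_standard`, `relapse_high`), each a list of dose rules with
#'   `inn`, `route`, `dose_basis` (`per_m2`, `per_kg` or `fixed`),
#'   `dose_amount` (per administration, in the basis' units),
#'   `n_administrations` (per full course) and optionally `age_bands` (a list
#'   restricting the rule to certain bands) and `phase` (free-text metadata;
#'   treatment phases do not affect the course total).
#'
#' A formulation is identified by the pair (inn, route); the package labels it
#' `"inn:route"`. Parenteral status (vial-administered) is derived: every
#' non-oral route is parenteral.
#'
#' @param path Path to a YAML file.
#' @return A `protocol_set`: a list with tibbles `formulary` and `rules`.
#' @export
read_protocols <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("protocol file not found: '%s'", path))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_config(sprintf("could not parse protocol YAML '%s': %s", path, conditionMessage(e)))
  })
  for (key in c("formulary", "arms")) {
    if (is.null(raw[[key]])) {
      stop_config(sprintf("protocol file '%s' lacks top-level key '%s'", path, key))
    }
  }
  meds <- dplyr::bind_rows(lapply(raw$formulary$medicines, function(m) {
    tibble::tibble(
      inn = require_field(m, "inn", path, "medicine"),
      drug_class = require_field(m, "drug_class", path, "medicine")
    )
  }))
  forms <- dplyr::bind_rows(lapply(raw$formulary$formulations, function(f) {
    tibble::tibble(
      inn = require_field(f, "inn", path, "formulation"),
      route = require_field(f, "route", path, "formulation"),
      smallest_unit_strength = as.numeric(require_field(
        f, "smallest_unit_strength", path, "formulation"
      )),
      unit_kind = require_field(f, "unit_kind", path, "formulation"),
      predominantly_paediatric_all = isTRUE(f$predominantly_paediatric_all)
    )
  }))
  rules <- dplyr::bind_rows(lapply(names(raw$arms), function(arm) {
    dplyr::bind_rows(lapply(raw$arms[[arm]], function(r) {
      tibble::tibble(
        arm = arm,
        inn = require_field(r, "inn", path, "dose rule"),
        route = require_field(r, "route", path, "dose rule"),
        dose_basis = require_field(r, "dose_basis", path, "dose rule"),
        dose_amount = as.numeric(require_field(r, "dose_amount", path, "dose rule")),
        n_administrations = as.numeric(require_field(
          r, "n_administrations", path, "dose rule"
        )),
        age_bands = list(if (is.null(r$age_bands)) NULL else as.character(r$age_bands)),
        phase = as.character(r$phase %||% NA_character_)
      )
    }))
  }))
  new_protocol_set(meds, forms, rules)
}

require_field <- function(x, field, path, what) {
  if (is.null(x[[field]])) {
    stop_config(sprintf("%s entry in '%s' lacks required field '%s'", what, path, field))
  }
  x[[field]]
}

formulation_label <- function(inn, route) paste(inn, route, sep = ":")

protocol_arms <- c("standard", "high", "relapse_standard", "relapse_high")

new_protocol_set <- function(medicines, formulations, rules) {
  formulations$formulation <- formulation_label(formulations$inn, formulations$route)
  formulations$parenteral <- formulations$route != "oral"
  i <- match(formulations$inn, medicines$inn)
  formulations$drug_class <- medicines$drug_class[i]
  rules$formulation <- formulation_label(rules$inn, rules$route)
  structure(
    list(medicines = medicines, formulary = formulations, rules = rules),
    class = "protocol_set"
  )
}

#' @export
print.protocol_set <- function(x, ...) {
  cat(sprintf(
    "<protocol_set> %d medicines, %d formulations, %d dose rules across arms: %s\n",
    nrow(x$medicines), nrow(x$formulary), nrow(x$rules),
    paste(unique(x$rules$arm), collapse = ", ")
  ))
  invisible(x)
}

#' Validate a protocol set
#'
#' Checks structural completeness: all four protocol arms present, every dose
#' rule referencing a known formulation, positive doses and administration
#' counts, positive smallest-unit strengths, unique medicine names, and no
#' duplicate (arm, formulation, age constraint) rules.
#'
#' @param protocols A `protocol_set`, as from [read_protocols()].
#' @param strict If `TRUE`, raise a validation error on any violation instead
#'   of returning the report.
#' @return Character vector of violations (empty when valid), invisibly a
#'   `protocol_validation` object.
#' @export
validate_protocol_set <- function(protocols, strict = FALSE) {
  v <- character()
  missing_arms <- setdiff(protocol_arms, unique(protocols$rules$arm))
  if (length(missing_arms)) {
    v <- c(v, sprintf("missing arm: %s", missing_arms))
  }
  extra_arms <- setdiff(unique(protocols$rules$arm), protocol_arms)
  if (length(extra_arms)) {
    v <- c(v, sprintf("unknown arm: %s", extra_arms))
  }
  if (anyDuplicated(protocols$medicines$inn)) {
    v <- c(v, sprintf(
      "duplicate medicine: %s",
      unique(protocols$medicines$inn[duplicated(protocols$medicines$inn)])
    ))
  }
  if (anyNA(protocols$formulary$drug_class)) {
    v <- c(v, sprintf(
      "formulation '%s' references a medicine absent from the formulary",
      protocols$formulary$formulation[is.na(protocols$formulary$drug_class)]
    ))
  }
  bad_class <- !protocols$medicines$drug_class %in% c("antineoplastic", "chemoprotective")
  if (any(bad_class)) {
    v <- c(v, sprintf(
      "medicine '%s' has unknown drug_class '%s'",
      protocols$medicines$inn[bad_class], protocols$medicines$drug_class[bad_class]
    ))
  }
  bad_strength <- !is.finite(protocols$formulary$smallest_unit_strength) |
    protocols$formulary$smallest_unit_strength <= 0
  if (any(bad_strength)) {
    v <- c(v, sprintf(
      "formulation '%s' has non-positive smallest_unit_strength",
      protocols$formulary$formulation[bad_strength]
    ))
  }
  bad_kind <- !protocols$formulary$unit_kind %in% c("mg", "active_units")
  if (any(bad_kind)) {
    v <- c(v, sprintf(
      "formulation '%s' has unknown unit_kind '%s'",
      protocols$formulary$formulation[bad_kind], protocols$formulary$unit_kind[bad_kind]
    ))
  }
  r <- protocols$rules
  unknown <- !r$formulation %in% protocols$formulary$formulation
  if (any(unknown)) {
    v <- c(v, sprintf(
      "dose rule in arm '%s' references unknown formulation '%s'",
      r$arm[unknown], r$formulation[unknown]
    ))
  }
  bad_dose <- !is.finite(r$dose_amount) | r$dose_amount <= 0
  if (any(bad_dose)) {
    v <- c(v, sprintf(
      "dose rule for '%s' in arm '%s' has non-positive dose_amount %s",
      r$formulation[bad_dose], r$arm[bad_dose], format(r$dose_amount[bad_dose])
    ))
  }
  bad_n <- !is.finite(r$n_administrations) | r$n_administrations < 1 |
    r$n_administrations != floor(r$n_administrations)
  if (any(bad_n)) {
    v <- c(v, sprintf(
      "dose rule for '%s' in arm '%s' has invalid n_administrations",
      r$formulation[bad_n], r$arm[bad_n]
    ))
  }
  bad_basis <- !r$dose_basis %in% c("per_m2", "per_kg", "fixed")
  if (any(bad_basis)) {
    v <- c(v, sprintf(
      "dose rule for '%s' in arm '%s' has unknown dose_basis '%s'",
      r$formulation[bad_basis], r$arm[bad_basis], r$dose_basis[bad_basis]
    ))
  }
  key <- paste(r$arm, r$formulation,
               vapply(r$age_bands, function(b) paste(b %||% "*", collapse = "|"), ""))
  if (anyDuplicated(key)) {
    v <- c(v, sprintf("duplicate dose rule: %s", unique(key[duplicated(key)])))
  }
  if (strict && length(v)) {
    stop_validation(paste(c("invalid protocol set:", v), collapse = "\n  - "))
  }
  structure(v, class = c("protocol_validation", class(v)))
}

#' @export
print.protocol_validation <- function(x, ...) {
  if (length(x) == 0) {
    cat("protocol set valid: no violations\n")
  } else {
    cat(sprintf("protocol set INVALID: %d violation(s)\n", length(x)))
    cat(paste0("  - ", unclass(x), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write a protocol set to YAML
#'
#' Inverse of [read_protocols()]: the written file reloads to an equal
#' protocol set.
#'
#' @param protocols A `protocol_set`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_protocols <- function(protocols, path) {
  raw <- list(
    formulary = list(
      medicines = lapply(seq_len(nrow(protocols$medicines)), function(i) {
        list(inn = protocols$medicines$inn[i],
             drug_class = protocols$medicines$drug_class[i])
      }),
      formulations = lapply(seq_len(nrow(protocols$formulary)), function(i) {
        f <- protocols$formulary[i, ]
        out <- list(
          inn = f$inn, route = f$route,
          smallest_unit_strength = f$smallest_unit_strength,
          unit_kind = f$unit_kind
        )
        if (f$predominantly_paediatric_all) out$predominantly_paediatric_all <- TRUE
        out
      })
    ),
    arms = lapply(split(protocols$rules, protocols$rules$arm), function(rr) {
      lapply(seq_len(nrow(rr)), function(i) {
        r <- rr[i, ]
        out <- list(
          inn = r$inn, route = r$route, dose_basis = r$dose_basis,
          dose_amount = r$dose_amount, n_administrations = r$n_administrations
        )
        if (!is.null(r$age_bands[[1]])) out$age_bands <- as.list(r$age_bands[[1]])
        if (!is.na(r$phase)) out$phase <- r$phase
        out
      })
    })
  )
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' Per-patient course requirement for one protocol arm
#'
#' Totals the amount of each formulation one child needs for a full course on
#' the given arm: for every applicable dose rule,
#' `dose_amount * basis factor * n_administrations`, where the basis factor is
#' the child's BSA (`per_m2`), weight (`per_kg`) or 1 (`fixed`); amounts are
#' summed per formulation across the arm's rules. Rules carrying an age-band
#' constraint are skipped when the band does not match.
#'
#' @param protocols A `protocol_set`.
#' @param arm Protocol arm label.
#' @param age_band Age band of the patient (used for age-constrained rules).
#' @param bsa Body surface area in m^2, strictly positive.
#' @param weight_kg Weight in kg; required only if a `per_kg` rule applies.
#' @return Named numeric vector: total amount per course, one entry per
#'   formulation (names are `"inn:route"` labels), in each formulation's
#'   `unit_kind`.
#' @export
per_patient_requirement <- function(protocols, arm, age_band, bsa, weight_kg = NULL) {
  check_positive_finite(bsa, "bsa")
  if (!arm %in% protocols$rules$arm) {
    stop_config(sprintf(
      "no protocol for arm '%s' (arms available: %s)",
      arm, paste(unique(protocols$rules$arm), collapse = ", ")
    ))
  }
  r <- protocols$rules[protocols$rules$arm == arm, , drop = FALSE]
  applies <- vapply(r$age_bands, function(b) is.null(b) || age_band %in% b, TRUE)
  r <- r[applies, , drop = FALSE]
  factor <- numeric(nrow(r))
  factor[r$dose_basis == "per_m2"] <- bsa
  factor[r$dose_basis == "fixed"] <- 1
  if (any(r$dose_basis == "per_kg")) {
    if (is.null(weight_kg)) {
      stop_usage(sprintf(
        "arm '%s' contains per_kg dose rules but no weight was supplied", arm
      ))
    }
    check_positive_finite(weight_kg, "weight_kg")
    factor[r$dose_basis == "per_kg"] <- weight_kg
  }
  amount <- r$dose_amount * factor * r$n_administrations
  out <- tapply(amount, r$formulation, sum)
  stats::setNames(as.numeric(out), names(out))
}
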