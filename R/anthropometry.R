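#' Body surface area by the Mosteller formula
#'
#' Computes body surface area (BSA) in square metres from height and weight,
#' `sqrt(height_cm * weight_kg / 3600)`. BSA is the standard scaling basis for
#' chemotherapy dosing in paediatric oncology; the Mosteller formula is the
#' simplest widely used estimator and the one this package assumes throughout.
#'
#' @param height_cm Height in centimetres; strictly positive and finite.
#' @param weight_kg Weight in kilograms; strictly positive and finite.
#'
#' @return Numeric vector of body surface areas in m^2.
#'
#' @examples
#' bsa_mosteller(100, 36)      # exactly 1 m^2
#' bsa_mosteller(110, 18.9)    # a typical 5-year-old, ~0.76 m^2
#' @export
bsa_mosteller <- function(height_cm, weight_kg) {
  check_positive_finite(height_cm, "height_cm")
  check_positive_finite(weight_kg, "weight_kg")
  sqrt(height_cm * weight_kg / 3600)
}

check_positive_finite <- function(x, field) {
  if (!is.numeric(x) || length(x) == 0) {
    stop_domain(sprintf("'%s' must be numeric and non-empty", field))
  }
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    stop_domain(sprintf(
      "'%s' must be strictly positive and finite (offending value(s): %s)",
      field, paste(format(x[bad]), collapse = ", ")
    ))
  }
  invisible(x)
}

#' Read an anthropometric reference table
#'
#' The reference table carries one row per age band with the mean height and
#' weight of children in that band; it is the source for the one-BSA-per-band
#' dosing basis used by [aggregate_need()]. Columns (exact header match):
#' `age_band`, `mean_height_cm`, `mean_weight_kg`.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `age_band`, `mean_height_cm`, `mean_weight_kg`.
#' @export
read_anthropometry <- function(path) {
  ref <- read_strict_csv(path, c("age_band", "mean_height_cm", "mean_weight_kg"))
  ref$age_band <- as.character(ref$age_band)
  if (anyDuplicated(ref$age_band)) {
    stop_data(sprintf(
      "duplicate age bands in anthropometric reference '%s': %s",
      path, paste(unique(ref$age_band[duplicated(ref$age_band)]), collapse = ", ")
    ))
  }
  check_positive_finite(ref$mean_height_cm, "mean_height_cm")
  check_positive_finite(ref$mean_weight_kg, "mean_weight_kg")
  tibble::as_tibble(ref)
}

#' Mean body surface area for one age band
#'
#' Applies the Mosteller formula to the band's mean height and mean weight,
#' giving one representative BSA per band (not the mean of individual BSAs).
#'
#' @param ref Anthropometric reference, as from [read_anthropometry()].
#' @param age_band Age band label present in `ref`.
#' @return BSA in m^2 (length-1 numeric).
#' @export
mean_bsa_for_band <- function(ref, age_band) {
  i <- match(age_band, ref$age_band)
  if (is.na(i)) {
    stop_data(sprintf(
      "age band '%s' not in anthropometric reference (available: %s)",
      age_band, paste(ref$age_band, collapse = ", ")
    ))
  }
  bsa_mosteller(ref$mean_height_cm[i], ref$mean_weight_kg[i])
}

#' Body surface area for every band in a reference table
#'
#' @param ref Anthropometric reference, as from [read_anthropometry()].
#' @return A tibble with columns `age_band` and `bsa` (m^2).
#' @export
band_bsa <- function(ref) {
  tibble::tibble(
    age_band = ref$age_band,
    bsa = bsa_mosteller(ref$mean_height_cm, ref$mean_weight_kg)
  )
}
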