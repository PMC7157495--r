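#' Column schema of a prescription extract CSV
#' @return Named character vector mapping column name to type
#'   (`"character"`, `"numeric"`, `"datetime"`, `"logical"`).
#' @export
prescription_schema <- function() {
  c(rx_id = "character", patient_id = "character", drug_name = "character",
    route = "character", formulation = "character", strength_mg = "numeric",
    discrete_dose = "character", frequency_label = "character",
    quantity = "numeric", written_duration_value = "numeric",
    written_duration_unit = "character", ordered_at = "datetime",
    is_refill = "logical")
}

#' Read a prescription extract CSV
#'
#' One row per prescription; header names must match [prescription_schema()]
#' exactly. Empty strings are absent values. `ordered_at` is ISO-8601 and is
#' parsed as UTC; `is_refill` is `true`/`false`.
#'
#' @param path Path to the CSV.
#' @return A validated prescription tibble.
#' @export
read_prescriptions <- function(path) {
  cols <- readr::cols(
    rx_id = readr::col_character(),
    patient_id = readr::col_character(),
    drug_name = readr::col_character(),
    route = readr::col_character(),
    formulation = readr::col_character(),
    strength_mg = readr::col_double(),
    discrete_dose = readr::col_character(),
    frequency_label = readr::col_character(),
    quantity = readr::col_double(),
    written_duration_value = readr::col_double(),
    written_duration_unit = readr::col_character(),
    ordered_at = readr::col_datetime(),
    is_refill = readr::col_logical()
  )
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  progress = FALSE, show_col_types = FALSE))
  missing <- setdiff(names(prescription_schema()), header)
  if (length(missing)) {
    stop("input is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x <- readr::read_csv(path, col_types = cols, progress = FALSE, na = c("", "NA"))
  validate_prescriptions(x)
}

#' Validate a prescription tibble against the extract schema
#'
#' Checks column presence/types and the record invariants: positive strengths
#' and nonnegative quantities where present, and written duration value and
#' unit present or absent together.
#'
#' @param records A data frame in the extract schema.
#' @return The records as a tibble, invisibly validated.
#' @export
validate_prescriptions <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(names(prescription_schema()), names(records))
  if (length(missing)) {
    stop("input is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(!is.na(records$strength_mg) & records$strength_mg <= 0)) {
    stop("strength_mg must be positive where present", call. = FALSE)
  }
  if (any(!is.na(records$quantity) & records$quantity < 0)) {
    stop("quantity must be nonnegative where present", call. = FALSE)
  }
  mismatch <- xor(is.na(records$written_duration_value),
                  is.na(records$written_duration_unit))
  if (any(mismatch)) {
    stop(sum(mismatch), " record(s) have a written duration value without a ",
         "unit (or vice versa)", call. = FALSE)
  }
  if (!inherits(records$ordered_at, "POSIXct")) {
    records$ordered_at <- as.POSIXct(records$ordered_at, tz = "UTC")
  }
  records
}

#' Write prescription records to the extract CSV schema
#'
#' @param records Prescription tibble (extra columns are dropped).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_prescriptions_csv <- function(records, path) {
  records <- validate_prescriptions(records)
  out <- records[, names(prescription_schema())]
  out$ordered_at <- format(out$ordered_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  out$is_refill <- ifelse(out$is_refill, "true", "false")
  readr::write_csv(out, path, na = "")
  invisible(path)
}
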