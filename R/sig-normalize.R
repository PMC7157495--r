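#' Resolve the maximum dose per administration from a discrete-dose string
#'
#' The discrete dose is the per-administration dose as entered in the order,
#' either a single value (`"15 mg"`) or a range (`"10-15 mg"`, en dash
#' accepted). Ranged doses resolve to the top of the range — the
#' maximum-dose convention, which makes the resulting days supply the
#' shortest possible holding the other sig elements constant. Tablets per
#' administration is the resolved dose divided by the per-tablet strength and
#' may be fractional (half tablets); no rounding is applied here.
#'
#' Anything that does not match the `"A mg"` / `"A-B mg"` grammar — including
#' inverted ranges (A > B) and non-positive values — is a parse failure, not a
#' guess: both outputs are `NA` and the record is counted as uncomputable
#' downstream.
#'
#' @param discrete_dose Character vector of dose strings.
#' @param strength_mg Numeric vector of per-tablet strengths (mg), recycled.
#' @return A tibble with columns `max_dose_mg` and `tablets_per_administration`.
#' @export
#' @examples
#' resolve_max_dose(c("20-30 mg", "15 mg"), c(15, 15))
resolve_max_dose <- function(discrete_dose, strength_mg) {
  n <- max(length(discrete_dose), length(strength_mg))
  dose <- rep_len(as.character(discrete_dose), n)
  strength <- rep_len(as.numeric(strength_mg), n)

  num <- "([0-9]+(?:\\.[0-9]+)?)"
  pat <- paste0("^\\s*", num, "\\s*(?:[-–]\\s*", num, ")?\\s*mg\\s*$")
  m <- regmatches(dose, regexec(pat, dose, ignore.case = TRUE))

  lo <- hi <- rep(NA_real_, n)
  parsed <- !is.na(dose) & lengths(m) == 3L
  if (any(parsed)) {
    lo[parsed] <- as.numeric(vapply(m[parsed], `[`, "", 2L))
    hi[parsed] <- as.numeric(vapply(m[parsed], function(g) {
      if (g[3L] == "") g[2L] else g[3L]
    }, ""))
  }
  valid <- parsed & !is.na(lo) & lo > 0 & hi >= lo &
    !is.na(strength) & strength > 0

  tibble::tibble(
    max_dose_mg = ifelse(valid, hi, NA_real_),
    tablets_per_administration = ifelse(valid, hi / strength, NA_real_)
  )
}

#' Convert a written duration to days
#'
#' Prescribers may document the intended duration in days, weeks, hours,
#' months or number of doses. All comparisons are made in days, so other
#' units are converted: weeks x 7, months x 30, hours / 24, and doses divided
#' by the administrations-per-day rate (absent when that rate is unknown).
#' Unknown units convert to `NA` and are counted as excluded, never guessed.
#' The `converted` flag marks every record whose unit was not already days,
#' so the share of unit-converted records is reportable.
#'
#' @param value Numeric vector of written duration values (>= 0).
#' @param unit Character vector of unit labels (singular or plural).
#' @param administrations_per_day Numeric vector of daily rates (used only
#'   for the `doses` unit), recycled.
#' @param factors Named conversion factors to days for the time units.
#' @return A tibble with columns `days` and `converted` (logical; `NA` where
#'   `days` is absent).
#' @export
#' @examples
#' convert_written_duration(c(3, 2, 6), c("days", "weeks", "doses"),
#'                          administrations_per_day = c(NA, NA, 2))
convert_written_duration <- function(value, unit, administrations_per_day = NA_real_,
                                     factors = c(day = 1, week = 7,
                                                 hour = 1 / 24, month = 30)) {
  n <- max(length(value), length(unit), length(administrations_per_day))
  value <- rep_len(as.numeric(value), n)
  if (any(!is.na(value) & value < 0)) {
    stop("written duration values must be nonnegative", call. = FALSE)
  }
  unit <- canonical_label(rep_len(as.character(unit), n))
  unit <- sub("s$", "", unit) # singularize: days -> day, doses -> dose
  apd <- rep_len(as.numeric(administrations_per_day), n)

  days <- rep(NA_real_, n)
  for (u in names(factors)) {
    sel <- !is.na(unit) & unit == u
    days[sel] <- value[sel] * factors[[u]]
  }
  is_dose <- !is.na(unit) & unit == "dose"
  days[is_dose] <- ifelse(!is.na(apd[is_dose]) & apd[is_dose] > 0,
                          value[is_dose] / apd[is_dose], NA_real_)

  tibble::tibble(
    days = days,
    converted = ifelse(is.na(days), NA, !is.na(unit) & unit != "day")
  )
}

#' Normalize raw prescription records into computable sig quantities
#'
#' Adds, per record: `administrations_per_day` (via the frequency lexicon,
#' PRN-stripped), `max_dose_mg` and `tablets_per_administration` (via the
#' discrete-dose grammar, maximum-dose convention), `written_duration_days`
#' and `duration_unit_converted` (via unit conversion), and
#' `calculated_duration_days` (the days-supply formula). Absent inputs
#' propagate to absent outputs — no imputation anywhere; downstream stages
#' count every absence.
#'
#' @param records A prescription tibble in the extract schema
#'   (see [read_prescriptions()]).
#' @param lexicon Frequency lexicon tibble.
#' @return The input tibble with normalization columns appended; unmapped
#'   frequency labels are carried in the `"unmapped_labels"` attribute.
#' @export
normalize_prescriptions <- function(records, lexicon = default_frequency_lexicon()) {
  records <- tibble::as_tibble(records)
  apd <- map_frequency(records$frequency_label, lexicon)
  dose <- resolve_max_dose(records$discrete_dose, records$strength_mg)
  written <- convert_written_duration(records$written_duration_value,
                                      records$written_duration_unit, apd)
  out <- dplyr::mutate(
    records,
    administrations_per_day = as.numeric(apd),
    max_dose_mg = dose$max_dose_mg,
    tablets_per_administration = dose$tablets_per_administration,
    written_duration_days = written$days,
    duration_unit_converted = written$converted,
    calculated_duration_days = calculated_duration(
      .data$quantity, .data$strength_mg, dose$max_dose_mg, apd
    )
  )
  attr(out, "unmapped_labels") <- attr(apd, "unmapped")
  out
}
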