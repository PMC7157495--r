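#' Days supply of a dispensed prescription ("calculated duration")
#'
#' The days the dispensed quantity lasts when taken at the maximum prescribed
#' dose and frequency:
#'
#' `((quantity x strength_mg) / max_dose_mg) / administrations_per_day`
#'
#' i.e. total possible administrations divided by administrations per day,
#' equivalently `quantity / (tablets_per_administration x
#' administrations_per_day)`. The result is exact and may be fractional; a
#' partial final administration contributes its fractional day. Any absent or
#' non-positive input yields `NA` — such records are counted as "calculated
#' duration could not be computed", never approximated.
#'
#' @param quantity Tablets dispensed.
#' @param strength_mg Per-tablet strength, mg.
#' @param max_dose_mg Maximum dose per administration, mg.
#' @param administrations_per_day Administrations per 24-hour day.
#' @return Numeric vector of days (`NA` where uncomputable).
#' @export
#' @examples
#' calculated_duration(c(12, 8, 20), 15, 30, 2) # 3, 2, 5 days
calculated_duration <- function(quantity, strength_mg, max_dose_mg,
                                administrations_per_day) {
  n <- max(length(quantity), length(strength_mg), length(max_dose_mg),
           length(administrations_per_day))
  q <- rep_len(as.numeric(quantity), n)
  s <- rep_len(as.numeric(strength_mg), n)
  d <- rep_len(as.numeric(max_dose_mg), n)
  a <- rep_len(as.numeric(administrations_per_day), n)
  ok <- !is.na(q) & !is.na(s) & !is.na(d) & !is.na(a) &
    q > 0 & s > 0 & d > 0 & a > 0
  out <- rep(NA_real_, n)
  out[ok] <- ((q[ok] * s[ok]) / d[ok]) / a[ok]
  out
}

#' Day-by-day consumption oracle
#'
#' Independent check on [calculated_duration()]: simulate a patient taking
#' `tablets_per_administration` tablets at each scheduled administration
#' (administrations evenly spaced, `administrations_per_day` per day) until
#' the supply cannot cover a full administration; a remaining partial
#' administration contributes its pro-rata fraction of the dosing interval.
#' Returns the elapsed schedule time in days. Agrees with the algebraic
#' formula on all valid inputs; it exists so the formula can be verified
#' against an explicit consumption process rather than against itself.
#'
#' @param quantity Tablets dispensed (positive scalar).
#' @param tablets_per_administration Tablets taken per administration.
#' @param administrations_per_day Administrations per day.
#' @return Elapsed days until the supply is exhausted (fractional).
#' @export
#' @examples
#' consumption_duration(12, 2, 2) # 3
#' consumption_duration(7, 2, 2)  # 1.75
consumption_duration <- function(quantity, tablets_per_administration,
                                 administrations_per_day) {
  stopifnot(length(quantity) == 1, quantity > 0,
            tablets_per_administration > 0, administrations_per_day > 0)
  remaining <- quantity
  full_admins <- 0L
  while (remaining >= tablets_per_administration) {
    remaining <- remaining - tablets_per_administration
    full_admins <- full_admins + 1L
  }
  partial <- remaining / tablets_per_administration
  (full_admins + partial) / administrations_per_day
}

#' Relationship categories
#'
#' The three-way classification of a written-versus-calculated duration pair.
#' `calc_greater` — the dispensed supply outlasts the documented duration —
#' is the guideline-relevant discrepancy.
#' @export
relationship_levels <- function() c("equal", "calc_greater", "calc_less")

#' Classify the written-versus-calculated duration relationship
#'
#' Three-way, total partition: `equal` when |written - calculated| <=
#' `tolerance`; `calc_greater` when the calculated duration exceeds the
#' written duration by more than the tolerance; `calc_less` otherwise. The
#' default tolerance of 1e-9 days is effectively exact comparison on rational
#' inputs, so a fractional days supply (say 2.5 days) never matches an
#' integer written duration; raise the tolerance for sensitivity analysis.
#'
#' @param written_days Written duration in days (>= 0).
#' @param calculated_days Calculated duration in days (> 0).
#' @param tolerance Equality half-width, days.
#' @return Factor with levels `equal`, `calc_greater`, `calc_less` (`NA`
#'   where either duration is absent).
#' @export
#' @examples
#' classify_relationship(3, c(3, 2, 5)) # equal, calc_less, calc_greater
classify_relationship <- function(written_days, calculated_days,
                                  tolerance = 1e-9) {
  n <- max(length(written_days), length(calculated_days))
  w <- rep_len(as.numeric(written_days), n)
  cd <- rep_len(as.numeric(calculated_days), n)
  if (any(!is.na(w) & w < 0)) {
    stop("written durations must be nonnegative", call. = FALSE)
  }
  diff <- cd - w
  out <- rep(NA_character_, n)
  ok <- !is.na(diff)
  out[ok & abs(diff) <= tolerance] <- "equal"
  out[ok & diff > tolerance] <- "calc_greater"
  out[ok & diff < -tolerance] <- "calc_less"
  factor(out, levels = relationship_levels())
}
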