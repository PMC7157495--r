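#' Empty cohort flow accounting
#'
#' One counter per step of the inclusion/exclusion cascade, in application
#' order: route/formulation filter, excluded-drug filter, missing written
#' duration, non-convertible written-duration unit, uncomputable calculated
#' duration, outside the study window. `n_unit_converted` counts records
#' whose written duration was converted to days (an annotation, not an
#' exclusion). Each record leaves the cascade exactly once, so
#' `n_total = n_final + sum(exclusions)` always holds.
#'
#' @return A list of class `cohort_flow` with all counters zero.
#' @export
cohort_flow <- function() {
  structure(list(
    n_total = 0L,
    n_excluded_route_form = 0L,
    n_excluded_drug = 0L,
    n_missing_written_duration = 0L,
    n_excluded_nonconvertible_unit = 0L,
    n_uncomputable_calculated = 0L,
    n_outside_window = 0L,
    n_unit_converted = 0L,
    n_final = 0L,
    n_pre = 0L,
    n_post = 0L
  ), class = "cohort_flow")
}

flow_exclusions <- function(flow) {
  flow$n_excluded_route_form + flow$n_excluded_drug +
    flow$n_missing_written_duration + flow$n_excluded_nonconvertible_unit +
    flow$n_uncomputable_calculated + flow$n_outside_window
}

#' @export
print.cohort_flow <- function(x, ...) {
  cat("Cohort flow\n")
  for (k in names(x)) cat(sprintf("  %-32s %d\n", k, x[[k]]))
  invisible(x)
}

#' @export
format.cohort_flow <- function(x, ...) {
  paste(sprintf("%s=%d", names(x), unlist(x)), collapse = ", ")
}

#' Apply the route/formulation and drug inclusion filters
#'
#' Fixed order: (1) records whose route is not oral or whose formulation is
#' not a tablet are excluded; (2) of the survivors, records whose drug name
#' contains an excluded-drug substring (case-insensitive; by default
#' buprenorphine and methadone, the opioid-use-disorder maintenance agents)
#' are excluded. Records with a missing route or formulation fail the oral-
#' tablet requirement and are excluded at step 1, counted, never dropped
#' silently.
#'
#' @param records Validated prescription tibble.
#' @param config An [audit_config()].
#' @return `list(included = tibble, flow = cohort_flow)`.
#' @export
apply_inclusion <- function(records, config = audit_config()) {
  records <- validate_prescriptions(records)
  flow <- cohort_flow()
  flow$n_total <- nrow(records)

  oral_tablet <- !is.na(records$route) & !is.na(records$formulation) &
    canonical_label(records$route) == "oral" &
    canonical_label(records$formulation) == "tablet"
  flow$n_excluded_route_form <- sum(!oral_tablet)
  records <- records[oral_tablet, ]

  name <- tolower(ifelse(is.na(records$drug_name), "", records$drug_name))
  excluded_drug <- rep(FALSE, nrow(records))
  for (drug in config$excluded_drugs) {
    excluded_drug <- excluded_drug | grepl(tolower(drug), name, fixed = TRUE)
  }
  flow$n_excluded_drug <- sum(excluded_drug)
  records <- records[!excluded_drug, ]

  list(included = records, flow = flow)
}

#' Build the written-versus-calculated comparison cohort
#'
#' Drops, in order and with separate counts: records with no written duration
#' documented at all; records whose written duration unit could not be
#' converted to days; and records whose calculated duration could not be
#' computed (unmapped frequency, unparseable dose, or absent quantity or
#' strength). Survivors are classified into the three relationship
#' categories. Unit-converted records among the survivors-of-the-written-
#' duration step are counted in `n_unit_converted`.
#'
#' @param normalized Output of [normalize_prescriptions()].
#' @param flow A `cohort_flow` carrying the upstream counts.
#' @param config An [audit_config()].
#' @return `list(comparisons = tibble, flow = cohort_flow)`; the comparison
#'   tibble has columns `rx_id`, `patient_id`, `ordered_at`, `is_refill`,
#'   `written_duration_days`, `calculated_duration_days`,
#'   `duration_unit_converted`, `category`.
#' @export
build_comparison_cohort <- function(normalized, flow = cohort_flow(),
                                    config = audit_config()) {
  x <- tibble::as_tibble(normalized)

  no_written <- is.na(x$written_duration_value)
  flow$n_missing_written_duration <- sum(no_written)
  x <- x[!no_written, ]

  nonconv <- is.na(x$written_duration_days)
  flow$n_excluded_nonconvertible_unit <- sum(nonconv)
  x <- x[!nonconv, ]
  flow$n_unit_converted <- sum(x$duration_unit_converted, na.rm = TRUE)

  uncomputable <- is.na(x$calculated_duration_days)
  flow$n_uncomputable_calculated <- sum(uncomputable)
  x <- x[!uncomputable, ]

  calc <- x$calculated_duration_days
  if (config$round_calculated) calc <- round(calc)
  comparisons <- tibble::tibble(
    rx_id = x$rx_id,
    patient_id = x$patient_id,
    ordered_at = x$ordered_at,
    is_refill = x$is_refill,
    written_duration_days = x$written_duration_days,
    calculated_duration_days = calc,
    duration_unit_converted = x$duration_unit_converted,
    category = classify_relationship(x$written_duration_days, calc,
                                     tolerance = config$tolerance_days)
  )
  flow$n_final <- nrow(comparisons)
  list(comparisons = comparisons, flow = flow)
}

#' Tally relationship categories
#'
#' @param categories Factor from [classify_relationship()].
#' @return A list of class `category_counts`: `n`, `equal`, `calc_greater`,
#'   `calc_less` (they sum to `n`).
#' @export
category_counts <- function(categories) {
  tab <- table(factor(categories, levels = relationship_levels()))
  structure(list(
    n = length(categories),
    equal = unname(tab[["equal"]]),
    calc_greater = unname(tab[["calc_greater"]]),
    calc_less = unname(tab[["calc_less"]])
  ), class = "category_counts")
}

#' Split the comparison cohort at the intervention boundary
#'
#' Records ordered strictly before the intervention timestamp are
#' preintervention; at or after it, postintervention. Records outside the
#' configured study window are excluded here and counted in the flow. The
#' split is a partition: pooled counts are the sums of the period counts.
#'
#' @param comparisons Comparison tibble from [build_comparison_cohort()].
#' @param config An [audit_config()].
#' @param flow Optional `cohort_flow` to update.
#' @return `list(pre, post, pooled, comparisons, flow)` where the first three
#'   are `category_counts` and `comparisons` gains a `period` column (window
#'   outliers removed).
#' @export
split_periods <- function(comparisons, config = audit_config(),
                          flow = cohort_flow()) {
  t <- comparisons$ordered_at
  in_window <- !is.na(t) & t >= config$study_start & t < config$study_end
  flow$n_outside_window <- flow$n_outside_window + sum(!in_window)
  flow$n_final <- sum(in_window)
  comparisons <- comparisons[in_window, ]
  pre <- comparisons$ordered_at < config$intervention_datetime
  comparisons$period <- factor(ifelse(pre, "pre", "post"),
                               levels = c("pre", "post"))
  flow$n_pre <- sum(pre)
  flow$n_post <- sum(!pre)
  list(
    pre = category_counts(comparisons$category[pre]),
    post = category_counts(comparisons$category[!pre]),
    pooled = category_counts(comparisons$category),
    comparisons = comparisons,
    flow = flow
  )
}

#' Monthly prescription volumes and per-patient-per-month counts
#'
#' The two utilization series compared pre/post: prescriptions per calendar
#' month (t test) and prescriptions per patient per month (Wilcoxon rank-sum;
#' heavily tied at a median of 1). Months are the calendar months of the
#' study window; months with no prescriptions count zero.
#'
#' @param records Prescription tibble (the post-inclusion population).
#' @param config An [audit_config()].
#' @return `list(monthly = tibble(month, period, n_rx),
#'   per_patient = tibble(month, period, patient_id, n_rx))`.
#' @export
monthly_volumes <- function(records, config = audit_config()) {
  t <- records$ordered_at
  keep <- !is.na(t) & t >= config$study_start & t < config$study_end
  records <- records[keep, ]
  month_seq <- seq(first_of_month(config$study_start),
                   by = "month", to = last_month_start(config$study_end))
  month_of <- format(records$ordered_at, "%Y-%m")
  month_lab <- format(month_seq, "%Y-%m")
  month_start_ts <- as.POSIXct(as.character(month_seq), tz = "UTC")
  period_of_month <- factor(
    ifelse(month_start_ts < config$intervention_datetime, "pre", "post"),
    levels = c("pre", "post")
  )
  monthly <- tibble::tibble(
    month = month_lab,
    period = period_of_month,
    n_rx = as.integer(table(factor(month_of, levels = month_lab)))
  )
  per_patient <- dplyr::count(
    tibble::tibble(month = month_of, patient_id = records$patient_id),
    .data$month, .data$patient_id, name = "n_rx"
  )
  per_patient$period <- factor(
    ifelse(per_patient$month < format(config$intervention_datetime, "%Y-%m"),
           "pre", "post"),
    levels = c("pre", "post")
  )
  list(monthly = monthly, per_patient = per_patient)
}

first_of_month <- function(x) as.Date(format(x, "%Y-%m-01"))

# start of the last month that begins strictly before study_end
last_month_start <- function(end) {
  d <- first_of_month(end)
  if (as.POSIXct(as.character(d), tz = "UTC") >= end) d <- seq(d, by = "-1 month", length.out = 2)[2]
  d
}
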