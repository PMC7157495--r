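#' Configuration for the synthetic prescription-extract generator
#'
#' The generator emulates a two-period outpatient opioid extract: monthly
#' order volumes drawn per calendar month, skewed patient assignment (median
#' 1 prescription per patient per month, IQR 1-2), a drug/strength catalog of
#' common oral opioid tablets, PRN-decorated frequency labels, ranged
#' discrete doses, refills, and period-specific corruption: missing written
#' durations (preferentially on refills, mirroring refills being exempt from
#' a documentation requirement), uncomputable sigs (unmappable frequency
#' text), and non-day written-duration units. Each record is assigned a
#' target relationship category and the dispense quantity is solved from it,
#' so the pipeline can be closed-loop tested against the configured mix.
#'
#' Defaults are a ~1/20 scale-down of a 22-month, ~92,000-prescription
#' two-period audit so that a full default run takes well under a second;
#' `profile = "study"` pins the full-scale magnitudes (monthly means 4284.64
#' pre / 4121.00 post, SDs 200.68 / 180.74, ~30,000 patients). Mix and
#' corruption defaults are the audit's observed period rates: missing
#' written duration 33.54% pre / 9.45% post, uncomputable 6.01% / 3.61%,
#' ranged doses ~4.5%, category mixes (equal, calc_greater, calc_less) =
#' (0.3886, 0.1795, 0.4319) pre and (0.4435, 0.1621, 0.3944) post.
#'
#' @param seed Integer seed; the generator consumes a single seeded stream
#'   in a fixed documented order, so identical configs are byte-identical.
#' @param profile `"scaled"` (default, ~1/20) or `"study"` (full scale).
#' @param months_pre,months_post Months in each period.
#' @param monthly_rx_mean,monthly_rx_sd Monthly order count distribution
#'   (normal, truncated at 0, rounded).
#' @param monthly_rx_mean_pre,monthly_rx_mean_post Optional per-period means;
#'   default to `monthly_rx_mean`.
#' @param n_patients Patient pool size.
#' @param p_missing_written_pre,p_missing_written_post Period probabilities
#'   of a blank written duration.
#' @param p_uncomputable_pre,p_uncomputable_post Period probabilities of an
#'   uncomputable sig (frequency replaced by unmappable free text).
#' @param p_ranged_dose Probability of a ranged discrete dose.
#' @param p_refill Probability a record is a refill.
#' @param relationship_mix_pre,relationship_mix_post Probabilities of
#'   (equal, calc_greater, calc_less); each must sum to 1.
#' @param p_nonoral Probability of a non-oral-tablet contaminant record.
#' @param p_excluded_drug Probability of a buprenorphine/methadone record.
#' @param p_nonday_unit Probability a written duration is documented in a
#'   non-day (but convertible) unit.
#' @param p_nonconvertible_unit Probability of an unconvertible duration
#'   unit (default 0).
#' @param written_duration_days,written_duration_weights Support and weights
#'   of the written-duration distribution (days).
#' @param study_start,intervention_datetime Calendar anchors; the post
#'   period starts at the intervention.
#' @return A list of class `rx_generator_config`.
#' @export
generator_config <- function(seed = 20171001,
                             profile = c("scaled", "study"),
                             months_pre = 11, months_post = 11,
                             monthly_rx_mean = NULL, monthly_rx_sd = NULL,
                             monthly_rx_mean_pre = NULL,
                             monthly_rx_mean_post = NULL,
                             n_patients = NULL,
                             p_missing_written_pre = 0.3354,
                             p_missing_written_post = 0.0945,
                             p_uncomputable_pre = 0.0601,
                             p_uncomputable_post = 0.0361,
                             p_ranged_dose = 0.045,
                             p_refill = 0.10,
                             relationship_mix_pre = c(equal = 0.3886,
                                                      calc_greater = 0.1795,
                                                      calc_less = 0.4319),
                             relationship_mix_post = c(equal = 0.4435,
                                                       calc_greater = 0.1621,
                                                       calc_less = 0.3944),
                             p_nonoral = 0.02,
                             p_excluded_drug = 0.01,
                             p_nonday_unit = 0.0364,
                             p_nonconvertible_unit = 0,
                             written_duration_days = c(1, 2, 3, 5, 7, 10, 14, 30),
                             written_duration_weights = c(0.08, 0.10, 0.30,
                                                          0.20, 0.17, 0.05,
                                                          0.07, 0.03),
                             study_start = "2017-10-01",
                             intervention_datetime = "2018-09-01") {
  profile <- match.arg(profile)
  scale <- if (profile == "study") 1 else 1 / 20
  if (is.null(monthly_rx_mean_pre)) {
    monthly_rx_mean_pre <- if (is.null(monthly_rx_mean)) 4284.64 * scale else monthly_rx_mean
  }
  if (is.null(monthly_rx_mean_post)) {
    monthly_rx_mean_post <- if (is.null(monthly_rx_mean)) 4121.00 * scale else monthly_rx_mean
  }
  if (is.null(monthly_rx_sd)) monthly_rx_sd <- 200 * scale
  if (is.null(n_patients)) n_patients <- max(10L, as.integer(30426 * scale))

  cfg <- list(
    seed = as.integer(seed),
    months_pre = as.integer(months_pre), months_post = as.integer(months_post),
    monthly_rx_mean_pre = monthly_rx_mean_pre,
    monthly_rx_mean_post = monthly_rx_mean_post,
    monthly_rx_sd = monthly_rx_sd,
    n_patients = as.integer(n_patients),
    p_missing_written_pre = p_missing_written_pre,
    p_missing_written_post = p_missing_written_post,
    p_uncomputable_pre = p_uncomputable_pre,
    p_uncomputable_post = p_uncomputable_post,
    p_ranged_dose = p_ranged_dose,
    p_refill = p_refill,
    relationship_mix_pre = relationship_mix_pre,
    relationship_mix_post = relationship_mix_post,
    p_nonoral = p_nonoral,
    p_excluded_drug = p_excluded_drug,
    p_nonday_unit = p_nonday_unit,
    p_nonconvertible_unit = p_nonconvertible_unit,
    written_duration_days = written_duration_days,
    written_duration_weights = written_duration_weights,
    study_start = as_utc(study_start),
    intervention_datetime = as_utc(intervention_datetime)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "rx_generator_config")
}

validate_generator_config <- function(cfg) {
  probs <- cfg[grep("^p_", names(cfg))]
  if (any(unlist(probs) < 0 | unlist(probs) > 1)) {
    stop("generator probabilities must lie in [0, 1]", call. = FALSE)
  }
  for (mix in list(cfg$relationship_mix_pre, cfg$relationship_mix_post)) {
    if (length(mix) != 3 || any(mix < 0) || abs(sum(mix) - 1) > 1e-12) {
      stop("relationship mixes must be 3 nonnegative probabilities summing to 1",
           call. = FALSE)
    }
  }
  if (abs(sum(cfg$written_duration_weights) - 1) > 1e-9) {
    stop("written_duration_weights must sum to 1", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a generator configuration from a flat key-value (YAML) file
#' @param path Path to the YAML file; keys match [generator_config()]
#'   arguments.
#' @return An `rx_generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(generator_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown generator config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (k in c("relationship_mix_pre", "relationship_mix_post",
              "written_duration_days", "written_duration_weights")) {
    if (!is.null(raw[[k]])) raw[[k]] <- unlist(raw[[k]])
  }
  do.call(generator_config, raw)
}

# oral opioid tablet catalog: name, per-tablet strength (mg)
drug_catalog <- function() {
  tibble::tibble(
    drug_name = c("oxycodone 5 mg tablet", "oxycodone 10 mg tablet",
                  "hydrocodone-acetaminophen 5-325 mg tablet",
                  "morphine 15 mg tablet", "morphine 30 mg tablet",
                  "hydromorphone 2 mg tablet", "tramadol 50 mg tablet"),
    strength_mg = c(5, 10, 5, 15, 30, 2, 50),
    weight = c(0.30, 0.12, 0.25, 0.08, 0.04, 0.06, 0.15)
  )
}

# frequency labels used for computable sigs (all in the default lexicon)
frequency_catalog <- function() {
  tibble::tibble(
    label = c("daily", "twice a day", "three times a day", "four times a day",
              "every 4 hours", "every 6 hours", "every 12 hours",
              "every other day"),
    rate = c(1, 2, 3, 4, 6, 4, 2, 0.5),
    weight = c(0.10, 0.22, 0.20, 0.12, 0.16, 0.12, 0.06, 0.02)
  )
}

unmappable_sigs <- c("as directed", "per pain protocol", "see instructions",
                     "titrate to effect")

#' Solve the dispense quantity that realizes a target relationship category
#'
#' Inverse of the days-supply formula. For `equal` the quantity is the exact
#' product `written_days x tablets_per_administration x
#' administrations_per_day`. For `calc_greater` the product is inflated by a
#' uniform factor on (1.1, 3) and rounded up to a whole tablet; for
#' `calc_less` deflated by a factor on (0.3, 0.9) and rounded down (floor one
#' tablet). If rounding flips the category the factor is redrawn; if no
#' whole-tablet quantity can realize it (tiny products) the unrounded scaled
#' quantity is used so the category is always honored.
#'
#' @param category One of `"equal"`, `"calc_greater"`, `"calc_less"`
#'   (vectorized).
#' @param written_days,tablets_per_admin,administrations_per_day Positive
#'   numerics, recycled.
#' @return Numeric vector of quantities.
#' @export
quantity_for_category <- function(category, written_days, tablets_per_admin,
                                  administrations_per_day) {
  n <- max(length(category), length(written_days), length(tablets_per_admin),
           length(administrations_per_day))
  category <- rep_len(as.character(category), n)
  product <- rep_len(written_days, n) * rep_len(tablets_per_admin, n) *
    rep_len(administrations_per_day, n)
  stopifnot(all(product > 0))
  out <- product # equal: exact, possibly fractional

  up <- category == "calc_greater"
  if (any(up)) {
    q <- ceiling(product[up] * stats::runif(sum(up), 1.1, 3))
    flip <- q <= product[up]
    q[flip] <- ceiling(product[up][flip]) + 1 # smallest guaranteed exceedance
    out[up] <- q
  }
  down <- category == "calc_less"
  if (any(down)) {
    q <- pmax(1, floor(product[down] * stats::runif(sum(down), 0.3, 0.9)))
    flip <- q >= product[down]
    # whole tablets cannot undershoot (product <= 1): fall back to the
    # unrounded scaled quantity so the category is preserved
    q[flip] <- product[down][flip] * stats::runif(sum(flip), 0.3, 0.9)
    out[down] <- q
  }
  out
}

#' Generate a synthetic prescription extract
#'
#' Deterministic given the config (single seeded stream, fixed draw order).
#' See [generator_config()] for what is emulated.
#'
#' @param config An [generator_config()].
#' @return A prescription tibble in the extract schema, ordered by
#'   `ordered_at`, with the generation-truth columns dropped.
#' @export
#' @examples
#' rx <- generate_prescriptions(generator_config(seed = 1))
#' dplyr::count(rx, substr(ordered_at, 1, 4))
generate_prescriptions <- function(config = generator_config()) {
  validate_generator_config(config)
  withr::with_seed(config$seed, generate_impl(config))
}

generate_impl <- function(cfg) {
  # months are anchored at the intervention boundary: months_pre calendar
  # months end just before it, months_post start at it
  boundary <- first_of_month(cfg$intervention_datetime)
  pre_months <- if (cfg$months_pre > 0) {
    rev(seq(boundary, by = "-1 month", length.out = cfg$months_pre + 1)[-1])
  } else {
    as.Date(character())
  }
  post_months <- if (cfg$months_post > 0) {
    seq(boundary, by = "month", length.out = cfg$months_post)
  } else {
    as.Date(character())
  }
  months <- c(pre_months, post_months)
  is_pre <- seq_along(months) <= cfg$months_pre
  n_month <- pmax(0L, as.integer(round(stats::rnorm(
    length(months),
    mean = ifelse(is_pre, cfg$monthly_rx_mean_pre, cfg$monthly_rx_mean_post),
    sd = cfg$monthly_rx_sd
  ))))
  n <- sum(n_month)
  if (n == 0L) {
    return(validate_prescriptions(empty_extract()))
  }
  month_idx <- rep(seq_along(months), n_month)
  pre <- is_pre[month_idx]

  # patient assignment: per-month blocks of 1 + Geom(0.6) orders per patient
  patient_id <- character(n)
  for (m in seq_along(months)) {
    nm <- n_month[m]
    if (nm == 0L) next
    sizes <- 1L + stats::rgeom(nm, 0.6) # at most nm patients needed
    sizes <- sizes[cumsum(sizes) - sizes < nm]
    ids <- sample.int(cfg$n_patients, length(sizes),
                      replace = length(sizes) > cfg$n_patients)
    assigned <- rep(ids, sizes)[seq_len(nm)]
    patient_id[month_idx == m] <- sprintf("P%06d", assigned)
  }

  # timestamps uniform within the month
  month_start <- as.POSIXct(as.character(months[month_idx]), tz = "UTC")
  month_len <- as.numeric(
    as.POSIXct(as.character(seq(months[1], by = "month",
                                length.out = length(months) + 1)[-1]),
               tz = "UTC") -
      as.POSIXct(as.character(months), tz = "UTC"), units = "secs"
  )
  ordered_at <- month_start + stats::runif(n) * month_len[month_idx]

  drugs <- drug_catalog()
  drug_row <- sample.int(nrow(drugs), n, replace = TRUE, prob = drugs$weight)
  freqs <- frequency_catalog()
  freq_row <- sample.int(nrow(freqs), n, replace = TRUE, prob = freqs$weight)
  rate <- freqs$rate[freq_row]
  freq_label <- freqs$label[freq_row]
  prn <- stats::runif(n) < 0.4
  freq_label[prn] <- paste(freq_label[prn], "PRN")

  strength <- drugs$strength_mg[drug_row]
  ranged <- stats::runif(n) < cfg$p_ranged_dose
  tpa_high <- ifelse(ranged, sample(c(2, 3), n, replace = TRUE,
                                    prob = c(0.8, 0.2)), 1)
  discrete_dose <- ifelse(
    ranged,
    sprintf("%g-%g mg", strength, strength * tpa_high),
    sprintf("%g mg", strength)
  )
  tpa <- tpa_high # max-dose convention: top of range; singles are one tablet

  written_days <- sample(cfg$written_duration_days, n, replace = TRUE,
                         prob = cfg$written_duration_weights)
  mix <- rbind(cfg$relationship_mix_pre, cfg$relationship_mix_post)
  category <- character(n)
  for (p in 1:2) {
    sel <- if (p == 1) pre else !pre
    category[sel] <- sample(relationship_levels(), sum(sel), replace = TRUE,
                            prob = mix[p, ])
  }
  quantity <- quantity_for_category(category, written_days, tpa, rate)

  is_refill <- stats::runif(n) < cfg$p_refill

  # written-duration unit: mostly days; a convertible-unit fraction expressed
  # so the converted value equals the drawn written days exactly
  unit <- rep("days", n)
  value <- as.numeric(written_days)
  nonday <- stats::runif(n) < cfg$p_nonday_unit
  if (any(nonday)) {
    pick <- sample(c("weeks", "hours", "doses"), sum(nonday), replace = TRUE,
                   prob = c(0.3, 0.3, 0.4))
    pick[pick == "weeks" & written_days[nonday] %% 7 != 0] <- "hours"
    unit[nonday] <- pick
    w <- written_days[nonday]
    value[nonday] <- ifelse(pick == "weeks", w / 7,
                            ifelse(pick == "hours", w * 24, w * rate[nonday]))
  }
  badunit <- stats::runif(n) < cfg$p_nonconvertible_unit
  unit[badunit] <- "visits"

  # missing written duration, preferentially on refills, calibrated so the
  # overall period rate matches p_missing_written_*
  p_missing <- ifelse(pre, cfg$p_missing_written_pre, cfg$p_missing_written_post)
  p_ref <- pmin(1, 3 * p_missing)
  p_nonref <- pmax(0, (p_missing - cfg$p_refill * p_ref) / (1 - cfg$p_refill))
  missing <- stats::runif(n) < ifelse(is_refill, p_ref, p_nonref)
  value[missing] <- NA_real_
  unit[missing] <- NA_character_

  # uncomputable sigs: frequency replaced by unmappable free text
  p_unc <- ifelse(pre, cfg$p_uncomputable_pre, cfg$p_uncomputable_post)
  uncomputable <- stats::runif(n) < p_unc
  freq_label[uncomputable] <- sample(unmappable_sigs, sum(uncomputable),
                                     replace = TRUE)

  route <- rep("oral", n)
  formulation <- rep("tablet", n)
  drug_name <- drugs$drug_name[drug_row]

  # contaminants the inclusion filters must catch
  nonoral <- stats::runif(n) < cfg$p_nonoral
  if (any(nonoral)) {
    form_pick <- sample(c("film", "solution"), sum(nonoral), replace = TRUE)
    route[nonoral] <- ifelse(form_pick == "film", "buccal", "oral")
    formulation[nonoral] <- form_pick
  }
  oud_drug <- stats::runif(n) < cfg$p_excluded_drug
  if (any(oud_drug)) {
    drug_name[oud_drug] <- sample(
      c("buprenorphine-naloxone 8-2 mg tablet", "methadone 10 mg tablet"),
      sum(oud_drug), replace = TRUE
    )
  }

  out <- tibble::tibble(
    rx_id = sprintf("RX%07d", seq_len(n)),
    patient_id = patient_id,
    drug_name = drug_name,
    route = route,
    formulation = formulation,
    strength_mg = strength,
    discrete_dose = discrete_dose,
    frequency_label = freq_label,
    quantity = quantity,
    written_duration_value = value,
    written_duration_unit = unit,
    ordered_at = ordered_at,
    is_refill = is_refill
  )
  validate_prescriptions(out[order(out$ordered_at), ])
}

empty_extract <- function() {
  tibble::tibble(
    rx_id = character(), patient_id = character(), drug_name = character(),
    route = character(), formulation = character(), strength_mg = numeric(),
    discrete_dose = character(), frequency_label = character(),
    quantity = numeric(), written_duration_value = numeric(),
    written_duration_unit = character(),
    ordered_at = as.POSIXct(character(), tz = "UTC"), is_refill = logical()
  )
}
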