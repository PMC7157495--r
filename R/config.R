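#' Audit configuration
#'
#' Bundles the study window, the intervention boundary, the classification
#' tolerance and the exclusion lists. The intervention boundary is a
#' timestamp; records ordered strictly before it are preintervention, records
#' at or after it are postintervention.
#'
#' @param study_start,study_end Study window (records outside it are excluded
#'   and counted). ISO-8601 strings or POSIXct; end is exclusive.
#' @param intervention_datetime The pre/post boundary.
#' @param tolerance_days Equality tolerance for [classify_relationship()].
#' @param round_calculated Round calculated durations to whole days before
#'   classification (sensitivity analysis; default off).
#' @param excluded_drugs Drug-name substrings excluded from the cohort
#'   (case-insensitive); defaults to the opioid-use-disorder maintenance
#'   agents buprenorphine and methadone.
#' @param lexicon_path Optional site frequency-lexicon CSV merged over the
#'   built-in defaults.
#' @param ci_method `"wald"` (default) or `"wilson"` binomial intervals.
#' @param chisq_correct Apply Yates continuity correction (default off).
#' @param t_var_equal Pooled-variance t test instead of Welch (default off).
#' @return A list of class `rx_audit_config`.
#' @export
audit_config <- function(study_start = "2017-10-01",
                         study_end = "2019-08-01",
                         intervention_datetime = "2018-09-01",
                         tolerance_days = 1e-9,
                         round_calculated = FALSE,
                         excluded_drugs = c("buprenorphine", "methadone"),
                         lexicon_path = NULL,
                         ci_method = c("wald", "wilson"),
                         chisq_correct = FALSE,
                         t_var_equal = FALSE) {
  cfg <- list(
    study_start = as_utc(study_start),
    study_end = as_utc(study_end),
    intervention_datetime = as_utc(intervention_datetime),
    tolerance_days = as.numeric(tolerance_days),
    round_calculated = isTRUE(round_calculated),
    excluded_drugs = as.character(excluded_drugs),
    lexicon_path = lexicon_path,
    ci_method = match.arg(ci_method),
    chisq_correct = isTRUE(chisq_correct),
    t_var_equal = isTRUE(t_var_equal)
  )
  stopifnot(cfg$study_start < cfg$study_end, cfg$tolerance_days >= 0)
  structure(cfg, class = "rx_audit_config")
}

as_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, tz = "UTC"), tz = "UTC"))
  as.POSIXct(x, tz = "UTC")
}

#' Read an audit configuration from a flat key-value (YAML) file
#'
#' Keys match the arguments of [audit_config()]; unknown keys are an error so
#' typos fail loudly.
#'
#' @param path Path to the YAML config file.
#' @return An `rx_audit_config`.
#' @export
read_audit_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- names(formals(audit_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(audit_config, raw)
}
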