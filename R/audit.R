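#' Run the full written-versus-calculated duration audit
#'
#' End to end: validate the extract, apply the oral-tablet and drug filters,
#' normalize sigs, build the comparison cohort, split at the intervention
#' boundary, and compute every estimate and test of the audit: category
#' proportions with confidence intervals per period and pooled, per-category
#' 2x2 chi-squares and the 3x2 omnibus, pre/post comparisons of
#' missing-written-duration, uncomputable and ranged-dose rates, the monthly
#' volume t test and the per-patient-per-month Wilcoxon rank-sum.
#'
#' @param input Path to an extract CSV, or a prescription tibble.
#' @param config An [audit_config()].
#' @return A list of class `rx_audit` with elements `flow`, `counts`
#'   (`pre`/`post`/`pooled` category counts), `estimates` (tibble),
#'   `tests` (tibble), `comparisons` (per-prescription tibble), `volumes`,
#'   `unmapped_labels`, `config`, `provenance`.
#' @export
#' @examples
#' rx <- generate_prescriptions(generator_config(seed = 1))
#' audit <- run_audit(rx)
#' audit
run_audit <- function(input, config = audit_config()) {
  input_path <- NA_character_
  if (is.character(input)) {
    input_path <- input
    records <- read_prescriptions(input)
  } else {
    records <- validate_prescriptions(input)
  }
  lexicon <- frequency_lexicon(path = config$lexicon_path)

  inc <- apply_inclusion(records, config)
  normalized <- normalize_prescriptions(inc$included, lexicon)
  cc <- build_comparison_cohort(normalized, inc$flow, config)
  per <- split_periods(cc$comparisons, config, cc$flow)
  flow <- per$flow
  comparisons <- per$comparisons

  # period denominators of the post-inclusion population (for the missing /
  # uncomputable / ranged-dose rate comparisons)
  t0 <- normalized$ordered_at
  in_window <- !is.na(t0) & t0 >= config$study_start & t0 < config$study_end
  pop <- normalized[in_window, ]
  pop_pre <- pop$ordered_at < config$intervention_datetime
  n_pop <- c(pre = sum(pop_pre), post = sum(!pop_pre))
  missing_w <- is.na(pop$written_duration_value)
  uncomp <- is.na(pop$calculated_duration_days)
  ranged <- grepl("[0-9]\\s*[-–]\\s*[0-9]", ifelse(is.na(pop$discrete_dose),
                                                       "", pop$discrete_dose))

  estimates <- category_estimates(per, config)
  rate_rows <- list(
    missing_written = c(sum(missing_w[pop_pre]), sum(missing_w[!pop_pre])),
    uncomputable = c(sum(uncomp[pop_pre]), sum(uncomp[!pop_pre])),
    ranged_dose = c(sum(ranged[pop_pre]), sum(ranged[!pop_pre]))
  )
  for (nm in names(rate_rows)) {
    for (p in 1:2) {
      if (n_pop[p] > 0) {
        est <- proportion_ci(rate_rows[[nm]][p], n_pop[p],
                             method = config$ci_method)
        estimates <- dplyr::bind_rows(estimates, tibble::tibble(
          period = c("pre", "post")[p], measure = nm,
          count = est$count, n = est$n, percent = est$percent,
          ci_low = est$ci_low, ci_high = est$ci_high
        ))
      }
    }
  }

  vols <- monthly_volumes(inc$included, config)
  tests <- audit_tests(per, rate_rows, n_pop, vols, config)

  report <- list(
    flow = flow,
    counts = per[c("pre", "post", "pooled")],
    estimates = estimates,
    tests = tests,
    comparisons = comparisons,
    volumes = vols,
    unmapped_labels = attr(normalized, "unmapped_labels"),
    config = config,
    provenance = list(
      input = input_path,
      n_input = nrow(records),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      package_version = as.character(utils::packageVersion("rxaudit"))
    )
  )
  class(report) <- "rx_audit"
  report
}

category_estimates <- function(per, config) {
  out <- list()
  for (p in c("pre", "post", "pooled")) {
    cnt <- per[[p]]
    if (cnt$n == 0) next
    for (cat in relationship_levels()) {
      est <- proportion_ci(cnt[[cat]], cnt$n, method = config$ci_method)
      out[[length(out) + 1L]] <- tibble::tibble(
        period = p, measure = cat, count = est$count, n = est$n,
        percent = est$percent, ci_low = est$ci_low, ci_high = est$ci_high
      )
    }
  }
  dplyr::bind_rows(out)
}

audit_tests <- function(per, rate_rows, n_pop, vols, config) {
  rows <- list()
  add <- function(name, tr) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      test = name, statistic = tr$statistic, df = tr$df, p_value = tr$p_value,
      method = tr$test_name
    )
  }
  pre <- per$pre
  post <- per$post
  if (pre$n > 0 && post$n > 0) {
    for (cat in relationship_levels()) {
      ok <- (pre[[cat]] + post[[cat]]) > 0 &&
        (pre$n - pre[[cat]] + post$n - post[[cat]]) > 0
      if (ok) {
        add(paste0("category_", cat),
            suppressWarnings(
              two_proportion_test(pre[[cat]], pre$n, post[[cat]], post$n,
                                  correct = config$chisq_correct)
            ))
      }
    }
    tab <- rbind(
      pre = c(pre$equal, pre$calc_greater, pre$calc_less),
      post = c(post$equal, post$calc_greater, post$calc_less)
    )
    if (all(colSums(tab) > 0)) {
      add("category_omnibus", suppressWarnings(omnibus_chisq(tab)))
    }
  }
  if (all(n_pop > 0)) {
    for (nm in names(rate_rows)) {
      cts <- rate_rows[[nm]]
      if (sum(cts) > 0 && sum(n_pop - cts) > 0) {
        add(nm, suppressWarnings(
          two_proportion_test(cts[1], n_pop[1], cts[2], n_pop[2],
                              correct = config$chisq_correct)
        ))
      }
    }
  }
  m <- vols$monthly
  if (sum(m$n_rx) > 0 &&
      sum(m$period == "pre") >= 2 && sum(m$period == "post") >= 2) {
    tr <- tryCatch(
      t_test_means(m$n_rx[m$period == "pre"], m$n_rx[m$period == "post"],
                   var_equal = config$t_var_equal),
      error = function(e) NULL
    )
    if (!is.null(tr)) add("monthly_volume", tr)
  }
  pp <- vols$per_patient
  if (any(pp$period == "pre") && any(pp$period == "post")) {
    tr <- withCallingHandlers(
      wilcoxon_rank_sum(pp$n_rx[pp$period == "pre"],
                        pp$n_rx[pp$period == "post"]),
      warning = function(w) invokeRestart("muffleWarning")
    )
    add("per_patient_monthly", tr)
  }
  if (!length(rows)) {
    return(tibble::tibble(test = character(), statistic = numeric(),
                          df = numeric(), p_value = numeric(),
                          method = character()))
  }
  dplyr::bind_rows(rows)
}

#' @export
print.rx_audit <- function(x, ...) {
  f <- x$flow
  cat("Written-versus-calculated opioid duration audit\n")
  cat(sprintf("  extract: %d prescriptions; final comparison cohort: %d (pre %d / post %d)\n",
              f$n_total, f$n_final, f$n_pre, f$n_post))
  cat(sprintf("  excluded: %d route/formulation, %d drug, %d missing written duration,\n",
              f$n_excluded_route_form, f$n_excluded_drug,
              f$n_missing_written_duration))
  cat(sprintf("            %d non-convertible unit, %d uncomputable, %d outside window\n",
              f$n_excluded_nonconvertible_unit, f$n_uncomputable_calculated,
              f$n_outside_window))
  cat(sprintf("  written durations converted to days: %d\n", f$n_unit_converted))
  est <- x$estimates[x$estimates$measure %in% relationship_levels(), ]
  if (nrow(est)) {
    cat("  relationship mix (n, %, CI):\n")
    for (i in seq_len(nrow(est))) {
      e <- est[i, ]
      cat(sprintf("    %-6s %-12s %6d  %s%% (%s-%s)\n", e$period, e$measure,
                  e$count, fmt2(e$percent), fmt2(e$ci_low), fmt2(e$ci_high)))
    }
  }
  if (nrow(x$tests)) {
    cat("  tests:\n")
    for (i in seq_len(nrow(x$tests))) {
      t <- x$tests[i, ]
      cat(sprintf("    %-22s %-28s p = %s\n", t$test, t$method,
                  format.pval(t$p_value, digits = 3, eps = 1e-3)))
    }
  }
  invisible(x)
}

#' Write an audit report to disk
#'
#' Writes `comparisons.csv` (one row per cohort prescription), `summary.csv`
#' (category counts/percentages/CIs per period), `flow.csv` (the cohort
#' flow, one step per row), `report.json` (all estimates, tests, flow, config
#' echo and provenance at full precision) and `unmapped_labels.log`.
#'
#' @param report An `rx_audit` from [run_audit()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_audit_report <- function(report, dir) {
  stopifnot(inherits(report, "rx_audit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp <- report$comparisons
  comp$ordered_at <- format(comp$ordered_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(comp, file.path(dir, "comparisons.csv"), na = "")
  readr::write_csv(report$estimates, file.path(dir, "summary.csv"), na = "")
  flow <- report$flow
  readr::write_csv(tibble::tibble(step = names(flow),
                                  count = as.integer(unlist(flow))),
                   file.path(dir, "flow.csv"))
  cfg <- report$config
  cfg$study_start <- format(cfg$study_start, "%Y-%m-%dT%H:%M:%SZ")
  cfg$study_end <- format(cfg$study_end, "%Y-%m-%dT%H:%M:%SZ")
  cfg$intervention_datetime <- format(cfg$intervention_datetime,
                                      "%Y-%m-%dT%H:%M:%SZ")
  jsonlite::write_json(
    list(flow = unclass(report$flow), counts = lapply(report$counts, unclass),
         estimates = report$estimates, tests = report$tests,
         config = unclass(cfg), provenance = report$provenance),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null", pretty = TRUE
  )
  writeLines(as.character(report$unmapped_labels %||% character()),
             file.path(dir, "unmapped_labels.log"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Bar chart of the relationship mix per period
#'
#' @param report An `rx_audit`.
#' @return A ggplot object.
#' @export
plot_category_mix <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  est <- report$estimates
  est <- est[est$measure %in% relationship_levels() & est$period != "pooled", ]
  ggplot2::ggplot(est, ggplot2::aes(x = .data$measure, y = .data$percent,
                                    fill = .data$period)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.2) +
    ggplot2::labs(x = "written vs calculated duration", y = "% of cohort",
                  fill = "period")
}
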