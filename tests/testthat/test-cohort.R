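test_that("route/formulation and drug filters exclude in fixed order", {
  rx <- make_rx(n = 5,
                route = c("buccal", "oral", "oral", "oral", "oral"),
                formulation = c("film", "solution", "tablet", "tablet", "tablet"),
                drug_name = c("buprenorphine film", "oxycodone",
                              "Methadone HCl 10 mg tablet",
                              "BUPRENORPHINE-naloxone tablet",
                              "oxycodone 5 mg tablet"))
  inc <- apply_inclusion(rx)
  # the buccal buprenorphine leaves at the route step, not the drug step
  expect_equal(inc$flow$n_excluded_route_form, 2)
  expect_equal(inc$flow$n_excluded_drug, 2)
  expect_equal(inc$included$rx_id, "RX005")
})

test_that("missing route or formulation is excluded and counted, not dropped", {
  rx <- make_rx(n = 2, route = c(NA, "oral"), formulation = "tablet")
  inc <- apply_inclusion(rx)
  expect_equal(inc$flow$n_excluded_route_form, 1)
  expect_equal(inc$flow$n_total, 2)
})

test_that("comparison cohort accounting matches a study-shaped extract", {
  n_total <- 92462
  n_written <- 72364
  n_uncomp <- 50
  rx <- make_rx(n = n_total)
  rx$rx_id <- sprintf("RX%06d", seq_len(n_total))
  no_written <- seq_len(n_total) > n_written
  rx$written_duration_value[no_written] <- NA
  rx$written_duration_unit[no_written] <- NA
  rx$frequency_label[seq_len(n_uncomp)] <- "per protocol"
  inc <- apply_inclusion(rx)
  norm <- normalize_prescriptions(inc$included)
  cc <- build_comparison_cohort(norm, inc$flow)
  expect_equal(cc$flow$n_missing_written_duration, n_total - n_written)
  expect_equal(cc$flow$n_uncomputable_calculated, n_uncomp)
  expect_equal(cc$flow$n_final, 72314)
})

test_that("empty and fully-computable inputs are handled exactly", {
  empty <- make_rx(n = 0)
  inc <- apply_inclusion(empty)
  cc <- build_comparison_cohort(normalize_prescriptions(inc$included),
                                inc$flow)
  expect_equal(cc$flow$n_final, 0)
  expect_equal(unlist(cc$flow), unlist(cohort_flow()), ignore_attr = TRUE)

  ten <- make_rx(n = 10)
  inc10 <- apply_inclusion(ten)
  cc10 <- build_comparison_cohort(normalize_prescriptions(inc10$included),
                                  inc10$flow)
  expect_equal(cc10$flow$n_final, 10)
})

test_that("the intervention boundary is strict-before = pre", {
  cfg <- audit_config()
  rx <- make_rx(n = 3, ordered_at = cfg$intervention_datetime + c(-86400, 0, 1))
  inc <- apply_inclusion(rx, cfg)
  cc <- build_comparison_cohort(normalize_prescriptions(inc$included),
                                inc$flow, cfg)
  per <- split_periods(cc$comparisons, cfg, cc$flow)
  expect_equal(per$flow$n_pre, 1)
  expect_equal(per$flow$n_post, 2)
  expect_equal(per$pooled$equal, per$pre$equal + per$post$equal)
})

test_that("records outside the study window are excluded and counted", {
  cfg <- audit_config()
  rx <- make_rx(n = 2, ordered_at = c(cfg$study_start - 1,
                                      cfg$study_start + 86400))
  inc <- apply_inclusion(rx, cfg)
  cc <- build_comparison_cohort(normalize_prescriptions(inc$included),
                                inc$flow, cfg)
  per <- split_periods(cc$comparisons, cfg, cc$flow)
  expect_equal(per$flow$n_outside_window, 1)
  expect_equal(per$flow$n_final, 1)
})

test_that("flow conservation holds under randomized corruption", {
  set.seed(3)
  for (i in 1:5) {
    n <- 400
    rx <- make_rx(n = n)
    rx$rx_id <- sprintf("RX%04d", seq_len(n))
    rx$route[stats::runif(n) < 0.1] <- "buccal"
    rx$drug_name[stats::runif(n) < 0.1] <- "methadone 10 mg tablet"
    kill_written <- stats::runif(n) < 0.2
    rx$written_duration_value[kill_written] <- NA
    rx$written_duration_unit[kill_written] <- NA
    rx$written_duration_unit[!kill_written & stats::runif(n) < 0.05] <- "visits"
    rx$frequency_label[stats::runif(n) < 0.1] <- "as directed"
    inc <- apply_inclusion(rx)
    cc <- build_comparison_cohort(normalize_prescriptions(inc$included),
                                  inc$flow)
    per <- split_periods(cc$comparisons, audit_config(), cc$flow)
    f <- per$flow
    expect_equal(f$n_total,
                 f$n_final + f$n_excluded_route_form + f$n_excluded_drug +
                   f$n_missing_written_duration +
                   f$n_excluded_nonconvertible_unit +
                   f$n_uncomputable_calculated + f$n_outside_window)
    expect_equal(f$n_final, f$n_pre + f$n_post)
  }
})

test_that("monthly volumes count calendar months and patients", {
  cfg <- audit_config()
  rx <- make_rx(n = 4,
                patient_id = c("A", "A", "A", "B"),
                ordered_at = as.POSIXct(
                  c("2018-01-05", "2018-01-15", "2018-01-25", "2018-02-10"),
                  tz = "UTC"))
  v <- monthly_volumes(rx, cfg)
  expect_equal(nrow(v$monthly), 22) # every calendar month of the window
  expect_equal(v$monthly$n_rx[v$monthly$month == "2018-01"], 3L)
  expect_equal(sum(v$monthly$n_rx), 4L)
  jan_a <- v$per_patient$n_rx[v$per_patient$month == "2018-01" &
                                v$per_patient$patient_id == "A"]
  expect_equal(jan_a, 3L)
  expect_equal(as.character(unique(v$monthly$period[v$monthly$month < "2018-09"])),
               "pre")
})

test_that("uniform volumes give mean with zero spread", {
  cfg <- audit_config()
  months <- format(seq(as.Date("2017-10-01"), by = "month", length.out = 22),
                   "%Y-%m-15")
  rx <- make_rx(n = 220,
                ordered_at = as.POSIXct(rep(months, each = 10), tz = "UTC"))
  v <- monthly_volumes(rx, cfg)
  expect_equal(mean(v$monthly$n_rx), 10)
  expect_equal(stats::sd(v$monthly$n_rx), 0)
})
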