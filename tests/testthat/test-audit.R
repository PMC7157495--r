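test_that("auditing the three worked sig rows yields one of each category", {
  report <- run_audit(worked_example_rx())
  expect_equal(report$flow$n_final, 3)
  expect_equal(report$counts$pooled$equal, 1)
  expect_equal(report$counts$pooled$calc_greater, 1)
  expect_equal(report$counts$pooled$calc_less, 1)
  comp <- report$comparisons
  expect_equal(comp$calculated_duration_days, c(3, 2, 5))
  expect_equal(as.character(comp$category),
               c("equal", "calc_less", "calc_greater"))
})

test_that("an empty but valid extract audits to a zero report", {
  report <- run_audit(make_rx(n = 0))
  expect_equal(report$flow$n_final, 0)
  expect_equal(nrow(report$comparisons), 0)
  expect_equal(nrow(report$tests), 0)
})

test_that("schema violations are named errors", {
  bad <- make_rx(n = 2)
  bad$quantity <- NULL
  expect_error(run_audit(bad), "quantity")
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(data.frame(rx_id = "a", drug_name = "b"), path)
  expect_error(read_prescriptions(path), "missing required column")
})

test_that("extract CSV round-trips through write and read", {
  rx <- generate_prescriptions(generator_config(
    seed = 9, months_pre = 1, months_post = 1,
    monthly_rx_mean = 40, monthly_rx_sd = 4
  ))
  path <- withr::local_tempfile(fileext = ".csv")
  write_prescriptions_csv(rx, path)
  back <- read_prescriptions(path)
  expect_equal(nrow(back), nrow(rx))
  expect_equal(back$quantity, rx$quantity)
  expect_equal(back$written_duration_value, rx$written_duration_value)
  expect_equal(as.numeric(back$ordered_at), floor(as.numeric(rx$ordered_at)))
  expect_identical(back$is_refill, rx$is_refill)
})

test_that("generate-then-audit succeeds across fuzzed configs", {
  set.seed(2024)
  for (i in 1:50) {
    mix_pre <- stats::runif(3)
    mix_pre <- mix_pre / sum(mix_pre)
    mix_post <- stats::runif(3)
    mix_post <- mix_post / sum(mix_post)
    cfg <- generator_config(
      seed = 1000 + i,
      months_pre = sample(0:3, 1), months_post = sample(1:3, 1),
      monthly_rx_mean = stats::runif(1, 10, 60), monthly_rx_sd = 5,
      p_missing_written_pre = stats::runif(1, 0, 0.5),
      p_missing_written_post = stats::runif(1, 0, 0.3),
      p_uncomputable_pre = stats::runif(1, 0, 0.1),
      p_uncomputable_post = stats::runif(1, 0, 0.1),
      p_ranged_dose = stats::runif(1, 0, 0.2),
      p_refill = stats::runif(1, 0, 0.3),
      relationship_mix_pre = mix_pre, relationship_mix_post = mix_post,
      p_nonoral = stats::runif(1, 0, 0.1),
      p_excluded_drug = stats::runif(1, 0, 0.05),
      p_nonday_unit = stats::runif(1, 0, 0.1),
      p_nonconvertible_unit = stats::runif(1, 0, 0.02)
    )
    rx <- generate_prescriptions(cfg)
    report <- run_audit(rx)
    f <- report$flow
    expect_equal(f$n_total,
                 f$n_final + f$n_excluded_route_form + f$n_excluded_drug +
                   f$n_missing_written_duration +
                   f$n_excluded_nonconvertible_unit +
                   f$n_uncomputable_calculated + f$n_outside_window)
    expect_equal(f$n_final, f$n_pre + f$n_post)
  }
})

test_that("report internals are mutually consistent and reconstructible", {
  rx <- generate_prescriptions(generator_config(
    seed = 4, months_pre = 2, months_post = 2,
    monthly_rx_mean = 80, monthly_rx_sd = 8
  ))
  report <- run_audit(rx)
  est <- report$estimates
  cat_est <- est[est$measure %in% relationship_levels(), ]
  for (i in seq_len(nrow(cat_est))) {
    e <- cat_est[i, ]
    cnt <- report$counts[[e$period]]
    expect_equal(e$count, cnt[[e$measure]])
    expect_equal(e$percent, 100 * e$count / e$n)
    expect_lte(e$ci_low, e$percent)
    expect_gte(e$ci_high, e$percent)
  }
  # percentages recomputable from the per-prescription table
  comp <- report$comparisons
  expect_equal(report$counts$pre$equal,
               sum(comp$category == "equal" & comp$period == "pre"))
})

test_that("written reports round-trip and echo the configuration", {
  rx <- generate_prescriptions(generator_config(
    seed = 6, months_pre = 1, months_post = 1,
    monthly_rx_mean = 30, monthly_rx_sd = 3
  ))
  report <- run_audit(rx)
  dir <- withr::local_tempdir()
  write_audit_report(report, dir)
  expect_setequal(list.files(dir),
                  c("comparisons.csv", "summary.csv", "flow.csv",
                    "report.json", "unmapped_labels.log"))
  j <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_equal(j$flow$n_final, report$flow$n_final)
  expect_equal(j$config$tolerance_days, report$config$tolerance_days)
  flow_csv <- readr::read_csv(file.path(dir, "flow.csv"),
                              show_col_types = FALSE)
  expect_equal(flow_csv$count[flow_csv$step == "n_final"],
               report$flow$n_final)
})

test_that("the command-line interface generates and audits end to end", {
  skip_on_os("windows")
  cli <- system.file("exec", "rxaudit", package = "rxaudit")
  skip_if(cli == "", "CLI script not installed")
  withr::local_envvar(R_LIBS = paste(.libPaths(),
                                     collapse = .Platform$path.sep))
  dir <- withr::local_tempdir()
  csv <- file.path(dir, "rx.csv")
  cfg_file <- file.path(dir, "gen.yaml")
  yaml::write_yaml(list(months_pre = 1, months_post = 1,
                        monthly_rx_mean = 25, monthly_rx_sd = 2), cfg_file)
  status <- system2("Rscript", c(cli, "generate", "--config", cfg_file,
                                 "--out", csv, "--seed", "11"),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0)
  expect_true(file.exists(csv))
  out_dir <- file.path(dir, "report")
  status2 <- system2("Rscript", c(cli, "audit", "--input", csv,
                                  "--out", out_dir),
                     stdout = FALSE, stderr = FALSE)
  expect_equal(status2, 0)
  expect_true(file.exists(file.path(out_dir, "report.json")))
  # determinism: same seed, same extract
  csv2 <- file.path(dir, "rx2.csv")
  system2("Rscript", c(cli, "generate", "--config", cfg_file,
                       "--out", csv2, "--seed", "11"),
          stdout = FALSE, stderr = FALSE)
  expect_identical(readLines(csv), readLines(csv2))
})
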