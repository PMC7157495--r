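# Build extract-schema prescription rows with sensible defaults; every field
# overridable per test.
make_rx <- function(n = 1, rx_id = sprintf("RX%03d", seq_len(n)),
                    patient_id = "P1", drug_name = "morphine 15 mg tablet",
                    route = "oral", formulation = "tablet", strength_mg = 15,
                    discrete_dose = "15-30 mg",
                    frequency_label = "twice a day PRN", quantity = 12,
                    written_duration_value = 3,
                    written_duration_unit = "days",
                    ordered_at = as.POSIXct("2018-01-15 12:00:00", tz = "UTC"),
                    is_refill = FALSE) {
  tibble::tibble(
    rx_id = rep_len(rx_id, n), patient_id = rep_len(patient_id, n),
    drug_name = rep_len(drug_name, n), route = rep_len(route, n),
    formulation = rep_len(formulation, n),
    strength_mg = rep_len(strength_mg, n),
    discrete_dose = rep_len(discrete_dose, n),
    frequency_label = rep_len(frequency_label, n),
    quantity = rep_len(quantity, n),
    written_duration_value = rep_len(written_duration_value, n),
    written_duration_unit = rep_len(written_duration_unit, n),
    ordered_at = rep_len(ordered_at, n), is_refill = rep_len(is_refill, n)
  )
}

digest_rows <- function(x) {
  paste(vapply(seq_len(nrow(x)), function(i) {
    paste(format(x[i, ]), collapse = "|")
  }, ""), collapse = "\n")
}

# the three worked sig rows: morphine 15 mg, 1-2 tablets BID PRN, written 3
# days, quantities 12 / 8 / 20
worked_example_rx <- function() {
  make_rx(n = 3, quantity = c(12, 8, 20))
}
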