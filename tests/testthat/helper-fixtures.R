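# build a paired-observation frame from a list of per-subject difference
# vectors; temperatures are laid out around 36.7 so diff/pair_mean stay
# consistent with the stored columns
make_pairs <- function(diff_by_subject, base_temp = 36.7) {
  rows <- lapply(seq_along(diff_by_subject), function(i) {
    d <- diff_by_subject[[i]]
    t_rec <- rep(base_temp, length(d))
    data.frame(patient_id = sprintf("S%02d", i),
               time_min = 2 * seq_along(d),
               t_dhf = t_rec + d, t_rec = t_rec,
               diff = d, pair_mean = t_rec + d / 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# one-sensor series data frame on the 2-min grid
make_series <- function(temps, start_min = 0) {
  data.frame(time_min = start_min + 2 * (seq_along(temps) - 1),
             temp_c = temps)
}

# long-format records for one patient with both sensors on a shared grid
make_patient_records <- function(id, dhf, rec) {
  rbind(
    data.frame(patient_id = id, sensor = "DHF",
               time_min = 2 * (seq_along(dhf) - 1), temp_c = dhf),
  data.frame(patient_id = id, sensor = "REC",
             time_min = 2 * (seq_along(rec) - 1), temp_c = rec)
  )
}

# balanced normal one-way differences: n subjects, m pairs each
simulate_diffs <- function(n, m, bias, sigma_b, sigma_w) {
  b <- stats::rnorm(n, 0, sigma_b)
  data.frame(patient_id = rep(sprintf("P%03d", seq_len(n)), each = m),
             diff = rep(bias + b, each = m) + stats::rnorm(n * m, 0, sigma_w))
}
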