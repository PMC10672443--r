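test_that("equilibration rule drops exactly the first two readings", {
  res <- clean_series(make_series(c(36.0, 36.2, 36.4, 36.5, 36.6)))
  expect_equal(res$retained$temp_c, c(36.4, 36.5, 36.6))
  expect_equal(res$report$n_discarded_equilibration, 2L)
  expect_equal(res$report$truncation_reason, "none")
  expect_equal(res$report$n_input,
               res$report$n_retained + res$report$n_discarded_equilibration +
                 res$report$n_discarded_after_truncation)
})

test_that("a change of more than 1 C censors the tail, exactly 1 C does not", {
  # pad two equilibration readings in front
  jump <- clean_series(make_series(c(36.0, 36.1, 36.5, 37.8, 37.9)))
  expect_equal(jump$retained$temp_c, 36.5)
  expect_equal(jump$report$truncation_reason, "jump")
  expect_equal(jump$report$truncation_time, 6)
  expect_equal(jump$report$n_discarded_after_truncation, 2L)

  boundary <- clean_series(make_series(c(36.0, 36.1, 36.5, 37.5, 37.6)))
  expect_equal(boundary$retained$temp_c, c(36.5, 37.5, 37.6))
  expect_equal(boundary$report$truncation_reason, "none")
})

test_that("a reading below 30 C censors the tail even if later values recover", {
  res <- clean_series(make_series(c(36.0, 36.1, 36.5, 29.9, 36.4)))
  expect_equal(res$retained$temp_c, 36.5)
  expect_equal(res$report$truncation_reason, "floor")
  # exactly 30.0 is retained (strict "below") but then jumps > 1 from 36.5
  res30 <- clean_series(make_series(c(36.0, 36.1, 36.5, 30.0, 30.1)))
  expect_equal(res30$report$truncation_reason, "jump")
  expect_equal(res30$retained$temp_c, 36.5)
})

test_that("empty and short series clean to empty without error", {
  res <- clean_series(make_series(numeric(0)))
  expect_equal(nrow(res$retained), 0L)
  expect_equal(res$report$n_input, 0L)
  short <- clean_series(make_series(c(36.5, 36.6)))
  expect_equal(nrow(short$retained), 0L)
  expect_equal(short$report$n_discarded_equilibration, 2L)
})

test_that("cleaning is idempotent and only ever censors a suffix", {
  set.seed(21)
  cfg0 <- cleaning_config(discard_first_n = 0L)
  for (k in 1:20) {
    temps <- 36.5 + cumsum(rnorm(sample(3:25, 1), 0, 0.45))
    if (runif(1) < 0.3) temps[sample(seq_along(temps), 1)] <- 28
    ser <- make_series(temps)
    once <- clean_series(ser)
    body <- ser[-(1:min(2, nrow(ser))), , drop = FALSE]
    # retained is a prefix of the post-equilibration series
    expect_equal(once$retained$temp_c,
                 utils::head(body$temp_c, nrow(once$retained)))
    twice <- clean_series(once$retained, cfg0)
    expect_equal(twice$retained, once$retained)
  }
})

test_that("streams pair on the shared grid and unpaired readings drop", {
  dhf <- make_series(c(36.5, 36.6, 36.7), start_min = 4)  # t = 4,6,8
  rec <- make_series(c(36.2, 36.3, 36.4), start_min = 6)  # t = 6,8,10
  pp <- pair_streams(dhf, rec, patient_id = "P9")
  expect_equal(pp$time_min, c(6, 8))
  expect_equal(pp$t_dhf, c(36.6, 36.7))
  expect_equal(pp$t_rec, c(36.2, 36.3))
  expect_equal(pp$diff, pp$t_dhf - pp$t_rec)
  expect_equal(pp$pair_mean, (pp$t_dhf + pp$t_rec) / 2)
  expect_equal(unique(pp$patient_id), "P9")

  expect_equal(nrow(pair_streams(make_series(numeric(0)),
                                 make_series(numeric(0)))), 0L)
  full <- pair_streams(make_series(rep(36.5, 20)), make_series(rep(36, 20)))
  expect_equal(nrow(full), 20L)
})

test_that("a positive pairing tolerance matches nearest-in-time readings", {
  cfg <- cleaning_config(pairing_tolerance_min = 1)
  dhf <- data.frame(time_min = c(0, 4.5), temp_c = c(36.5, 36.8))
  rec <- data.frame(time_min = c(0.5, 4, 10), temp_c = c(36.1, 36.2, 36.3))
  pp <- pair_streams(dhf, rec, cfg)
  expect_equal(nrow(pp), 2L)
  expect_equal(pp$t_rec, c(36.1, 36.2))
})

test_that("cohort cleaning truncates per stream and excludes empty overlaps", {
  set.seed(5)
  base <- 36.5 + cumsum(rnorm(8, 0, 0.1))
  r1 <- make_patient_records("P1", base + 0.4, base)
  dhf2 <- base + 0.4
  dhf2[5] <- 29.0   # floor artifact at 3rd retained DHF reading
  r2 <- make_patient_records("P2", dhf2, base)
  r3 <- make_patient_records("P3", base + 0.2, base)
  # P4: sensors on disjoint grids -> zero overlap -> excluded
  r4 <- rbind(
    data.frame(patient_id = "P4", sensor = "DHF",
               time_min = c(0, 2, 4, 6), temp_c = rep(36.5, 4)),
    data.frame(patient_id = "P4", sensor = "REC",
               time_min = c(8, 10, 12), temp_c = rep(36.2, 3))
  )
  out <- clean_cohort(rbind(r1, r2, r3, r4))
  cnt <- table(out$pairs$patient_id)
  expect_equal(as.integer(cnt[["P1"]]), 6L)   # 8 readings - 2 equilibration
  expect_equal(as.integer(cnt[["P3"]]), 6L)
  expect_equal(as.integer(cnt[["P2"]]), 2L)   # truncated at the artifact
  expect_equal(out$excluded, "P4")
  rep2 <- out$report[out$report$patient_id == "P2" &
                     out$report$sensor == "DHF", ]
  expect_equal(rep2$truncation_reason, "floor")
  # the intact REC stream of P2 continues past the DHF truncation
  repr <- out$report[out$report$patient_id == "P2" &
                     out$report$sensor == "REC", ]
  expect_equal(repr$truncation_reason, "none")
  # pair count never exceeds either stream length
  for (p in names(cnt)) {
    rp <- out$report[out$report$patient_id == p, ]
    expect_lte(as.integer(cnt[[p]]), min(rp$n_retained))
  }
})
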