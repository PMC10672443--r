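#' Cleaning rules for a single sensor stream
#'
#' Parameters of the per-stream artifact rules: the first `discard_first_n`
#' readings of every stream are dropped to allow the skin sensor to
#' equilibrate, and the remainder is scanned in time order for probe
#' dislocation - a change of more than `jump_threshold_c` between two
#' consecutive retained readings, or any reading below `floor_c`. At the
#' first offending reading the stream is censored (that reading and all
#' later ones discarded). Both inequalities are strict.
#'
#' @param discard_first_n number of initial equilibration readings to drop
#'   per stream (default 2).
#' @param jump_threshold_c dislocation jump threshold in degrees C
#'   (default 1.0); a change of exactly this size is retained.
#' @param floor_c dislocation floor in degrees C (default 30); a reading of
#'   exactly this value is retained.
#' @param interval_min nominal recording interval in minutes (default 2).
#' @param pairing_tolerance_min maximum |time difference| in minutes for two
#'   readings to be paired across sensors (default 0: exact grid match).
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(discard_first_n = 2L, jump_threshold_c = 1.0,
                            floor_c = 30.0, interval_min = 2,
                            pairing_tolerance_min = 0) {
  stopifnot(discard_first_n >= 0, jump_threshold_c > 0,
            floor_c > 0, floor_c < 45, interval_min > 0,
            pairing_tolerance_min >= 0)
  structure(list(discard_first_n = as.integer(discard_first_n),
                 jump_threshold_c = jump_threshold_c,
                 floor_c = floor_c,
                 interval_min = interval_min,
                 pairing_tolerance_min = pairing_tolerance_min),
            class = "cleaning_config")
}

#' Clean one (patient, sensor) series
#'
#' Applies the equilibration discard and the dislocation censoring rules to a
#' single time-sorted stream and reports what was removed.
#'
#' @param series data frame for one (patient, sensor), sorted by `time_min`,
#'   with columns `time_min` and `temp_c` (extra columns are carried along).
#' @param cfg a [cleaning_config()].
#' @return A list with `retained` (prefix of the post-equilibration series)
#'   and `report`: a one-row data frame with `n_input`,
#'   `n_discarded_equilibration`, `truncation_time` (`NA` if none),
#'   `truncation_reason` (`"jump"`, `"floor"` or `"none"`) and
#'   `n_discarded_after_truncation`.
#' @export
clean_series <- function(series, cfg = cleaning_config()) {
  stopifnot(is.data.frame(series))
  n_input <- nrow(series)
  if (n_input && is.unsorted(series$time_min, strictly = TRUE)) {
    stop("series must be strictly time-sorted", call. = FALSE)
  }
  n_eq <- min(cfg$discard_first_n, n_input)
  body <- if (n_input > n_eq) series[(n_eq + 1L):n_input, , drop = FALSE]
          else series[0, , drop = FALSE]
  cut_idx <- NA_integer_
  reason <- "none"
  if (nrow(body)) {
    temps <- body$temp_c
    # first reading below the floor, or jumping > threshold from the
    # previous retained reading, censors the tail
    for (i in seq_along(temps)) {
      if (temps[i] < cfg$floor_c) {
        cut_idx <- i; reason <- "floor"; break
      }
      if (i > 1L && abs(temps[i] - temps[i - 1L]) > cfg$jump_threshold_c) {
        cut_idx <- i; reason <- "jump"; break
      }
    }
  }
  if (is.na(cut_idx)) {
    retained <- body
    n_after <- 0L
    trunc_time <- NA_real_
  } else {
    retained <- body[seq_len(cut_idx - 1L), , drop = FALSE]
    n_after <- nrow(body) - cut_idx + 1L
    trunc_time <- body$time_min[cut_idx]
  }
  rownames(retained) <- NULL
  report <- data.frame(
    n_input = n_input,
    n_discarded_equilibration = n_eq,
    truncation_time = trunc_time,
    truncation_reason = reason,
    n_discarded_after_truncation = n_after,
    n_retained = nrow(retained),
    stringsAsFactors = FALSE
  )
  list(retained = retained, report = report)
}

#' Pair cleaned sensor streams by time
#'
#' Matches readings of the two cleaned streams of one patient on the shared
#' recording grid. With the default tolerance 0 only equal `time_min` values
#' pair; with a positive tolerance each DHF reading is matched to the nearest
#' reference reading within the tolerance (each used at most once). Unpaired
#' readings are dropped.
#'
#' @param dhf,rec cleaned data frames with `time_min`, `temp_c`.
#' @param cfg a [cleaning_config()] (supplies `pairing_tolerance_min`).
#' @param patient_id identifier stored in the output.
#' @return A paired-observation data frame with columns `patient_id`,
#'   `time_min`, `t_dhf`, `t_rec`, `diff` (`t_dhf - t_rec`) and `pair_mean`,
#'   sorted by time.
#' @export
pair_streams <- function(dhf, rec, cfg = cleaning_config(),
                         patient_id = "P1") {
  empty <- data.frame(patient_id = character(), time_min = numeric(),
                      t_dhf = numeric(), t_rec = numeric(),
                      diff = numeric(), pair_mean = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(dhf) || !nrow(rec)) return(empty)
  tol <- cfg$pairing_tolerance_min
  if (tol == 0) {
    idx_r <- match(dhf$time_min, rec$time_min)
    keep <- !is.na(idx_r)
    if (!any(keep)) return(empty)
    t_d <- dhf$time_min[keep]
    td <- dhf$temp_c[keep]
    tr <- rec$temp_c[idx_r[keep]]
  } else {
    used <- rep(FALSE, nrow(rec))
    t_d <- td <- tr <- numeric(0)
    for (i in seq_len(nrow(dhf))) {
      gap <- abs(rec$time_min - dhf$time_min[i])
      gap[used] <- Inf
      j <- which.min(gap)
      if (gap[j] <= tol) {
        used[j] <- TRUE
        t_d <- c(t_d, dhf$time_min[i])
        td <- c(td, dhf$temp_c[i])
        tr <- c(tr, rec$temp_c[j])
      }
    }
    if (!length(t_d)) return(empty)
  }
  out <- data.frame(patient_id = patient_id, time_min = t_d,
                    t_dhf = td, t_rec = tr,
                    diff = td - tr, pair_mean = (td + tr) / 2,
                    stringsAsFactors = FALSE)
  out <- out[order(out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clean and pair a whole cohort
#'
#' Applies [clean_series()] to every (patient, sensor) stream and
#' [pair_streams()] per patient; patients whose paired count falls below
#' `min_pairs` are excluded and listed.
#'
#' @param records validated long-format records (see [read_records()]).
#' @param cfg a [cleaning_config()].
#' @param min_pairs minimum retained pairs for a patient to stay in the
#'   analysis set (default 1).
#' @return A list with `pairs` (paired-observation data frame over retained
#'   patients), `report` (per-stream cleaning report with `patient_id` and
#'   `sensor` columns) and `excluded` (character vector of excluded patients).
#' @export
clean_cohort <- function(records, cfg = cleaning_config(), min_pairs = 1L) {
  records <- validate_records(records)
  patients <- unique(records$patient_id)
  reports <- list()
  pairs <- list()
  excluded <- character(0)
  for (p in patients) {
    sub <- records[records$patient_id == p, , drop = FALSE]
    cleaned <- list()
    for (s in SENSOR_LEVELS) {
      ser <- sub[sub$sensor == s, , drop = FALSE]
      res <- clean_series(ser, cfg)
      cleaned[[s]] <- res$retained
      rep_row <- cbind(data.frame(patient_id = p, sensor = s,
                                  stringsAsFactors = FALSE), res$report)
      reports[[length(reports) + 1L]] <- rep_row
    }
    pp <- pair_streams(cleaned$DHF, cleaned$REC, cfg, patient_id = p)
    if (nrow(pp) < min_pairs) {
      excluded <- c(excluded, p)
    } else {
      pairs[[length(pairs) + 1L]] <- pp
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else
    pair_streams(data.frame(), data.frame())
  report <- if (length(reports)) do.call(rbind, reports) else NULL
  rownames(pairs) <- rownames(report) <- NULL
  list(pairs = pairs, report = report, excluded = excluded)
}
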