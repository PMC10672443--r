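#' Descriptive summary of a paired cohort
#'
#' Per-sensor range, median and quartiles of the retained readings, and
#' per-patient pair counts with median and quartiles. Quartiles use linear
#' interpolation (R's default quantile type 7).
#'
#' @param pairs paired-observation data frame.
#' @return A list of class `cohort_summary` with `n_patients`, `n_pairs`,
#'   `pairs_per_patient` (min/q1/median/q3/max) and `sensors` (a data frame
#'   with one row per sensor).
#' @export
describe_cohort <- function(pairs) {
  if (!nrow(pairs)) stop("no pairs to describe", call. = FALSE)
  qq <- function(x) {
    q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }
  counts <- as.numeric(table(pairs$patient_id))
  sensors <- rbind(
    data.frame(sensor = "DHF", t(qq(pairs$t_dhf))),
    data.frame(sensor = "REC", t(qq(pairs$t_rec)))
  )
  structure(list(
    n_patients = length(counts),
    n_pairs = nrow(pairs),
    pairs_per_patient = qq(counts),
    sensors = sensors
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d pairs; pairs/patient median %s (quartiles %s-%s)\n",
              x$n_patients, x$n_pairs,
              format(x$pairs_per_patient[["median"]]),
              format(x$pairs_per_patient[["q1"]]),
              format(x$pairs_per_patient[["q3"]])))
  for (i in seq_len(nrow(x$sensors))) {
    s <- x$sensors[i, ]
    cat(sprintf("  %s: range %.1f-%.1f C, median %.1f (%.1f-%.1f)\n",
                s$sensor, s$min, s$max, s$median, s$q1, s$q3))
  }
  invisible(x)
}

#' Run the full agreement pipeline
#'
#' Cleans and pairs a long-format cohort, fits the repeated-measures limits
#' of agreement with the trend test, classifies the error grid and collects
#' everything into a study report. Optionally writes the intermediate
#' artifacts (pairs CSV, cleaning report, agreement and grid JSON) to a
#' directory.
#'
#' @param records long-format records (data frame or path readable by
#'   [read_records()]), or a [synthetic_config()] to simulate first.
#' @param config a [run_config()].
#' @param output_dir optional directory for artifact files.
#' @param min_pairs minimum retained pairs per patient (see
#'   [clean_cohort()]).
#' @return An object of class `study_report` with elements `cohort`
#'   ([describe_cohort()]), `agreement` ([zou_loa()]), `grid`
#'   ([summarize_grid()]), `cleaning` (per-stream report), `excluded`,
#'   `pairs`, `config`, `seed` (if simulated) and `version`.
#' @export
run_pipeline <- function(records, config = run_config(), output_dir = NULL,
                         min_pairs = 1L) {
  seed <- NULL
  if (inherits(records, "synthetic_config")) {
    seed <- records$seed
    records <- generate_cohort(records)$records
  } else if (is.character(records) && length(records) == 1L) {
    records <- read_records(records)
  }
  cleaned <- clean_cohort(records, config$cleaning, min_pairs = min_pairs)
  pairs <- cleaned$pairs
  if (!nrow(pairs)) stop("pipeline: no pairs retained after cleaning",
                         call. = FALSE)
  fit <- zou_loa(pairs, z = config$loa_z, conf_level = config$conf_level,
                 tolerance_c = config$grid$tolerance_c,
                 trend_method = config$trend_method)
  grid <- summarize_grid(pairs, config$grid)
  report <- structure(list(
    cohort = describe_cohort(pairs),
    agreement = fit,
    grid = grid,
    cleaning = cleaned$report,
    excluded = cleaned$excluded,
    pairs = pairs,
    config = config,
    seed = seed,
    version = as.character(utils::packageVersion("tempagree"))
  ), class = "study_report")
  if (!is.null(output_dir)) write_report_artifacts(report, output_dir)
  report
}

# serialize the report pieces as CSV/JSON artifacts
write_report_artifacts <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$pairs, file.path(dir, "pairs.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report$cleaning, file.path(dir, "cleaning.json"),
                       dataframe = "rows", na = "null", auto_unbox = TRUE,
                       digits = NA)
  fit <- report$agreement
  agree <- list(
    n_subjects = fit$n_subjects, n_pairs = fit$n_pairs,
    bias_c = fit$bias_c, sigma_b2 = fit$sigma_b2, sigma_w2 = fit$sigma_w2,
    sigma_d = fit$sigma_d,
    loa_lower_c = fit$loa_lower_c, loa_upper_c = fit$loa_upper_c,
    loa_halfwidth_c = fit$loa_halfwidth_c, se_loa_c = fit$se_loa_c,
    ci_bias = fit$ci_bias, ci_loa_lower = fit$ci_loa_lower,
    ci_loa_upper = fit$ci_loa_upper,
    prop_within_tolerance = fit$prop_within_tolerance,
    acceptable = fit$acceptable,
    trend = if (!is.null(fit$trend)) unclass(fit$trend)
  )
  jsonlite::write_json(agree, file.path(dir, "agreement.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  grid <- list(counts = as.list(report$grid$counts),
               percentages = as.list(report$grid$percentages),
               percent_no_wrong_decision =
                 report$grid$percent_no_wrong_decision,
               n_pairs = report$grid$n_pairs)
  jsonlite::write_json(grid, file.path(dir, "grid.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Paired temperature monitoring: agreement report ==\n")
  print(x$cohort)
  if (length(x$excluded)) {
    cat("  Excluded patients (too few pairs): ",
        paste(x$excluded, collapse = ", "), "\n", sep = "")
  }
  print(x$agreement)
  if (!is.null(x$agreement$trend)) print(x$agreement$trend)
  print(x$grid)
  invisible(x)
}
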