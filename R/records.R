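#' tempagree: agreement analysis for paired continuous temperature monitoring
#'
#' Tools for comparing a continuous non-invasive core-temperature sensor
#' against a reference probe: per-stream artifact cleaning, repeated-measures
#' Bland-Altman limits of agreement (Zou's variance-component method with
#' MOVER confidence intervals), a five-zone clinical error grid,
#' precision-based sample-size planning, and a synthetic cohort generator.
#'
#' @keywords internal
#' @aliases tempagree-package
"_PACKAGE"

SENSOR_LEVELS <- c("DHF", "REC")
RECORD_COLS <- c("patient_id", "sensor", "time_min", "temp_c")

#' Validate a long-format measurement record data frame
#'
#' Checks the invariants of the long measurement format: required columns,
#' finite temperatures, non-negative times, known sensor labels, no duplicate
#' (patient, sensor, time) keys, and strictly increasing times within each
#' (patient, sensor) series. Returns the records sorted by
#' (patient_id, sensor, time_min).
#'
#' @param records data frame with columns `patient_id`, `sensor` (`"DHF"` or
#'   `"REC"`), `time_min` (minutes from series start) and `temp_c` (degrees
#'   Celsius).
#' @return The validated, sorted data frame (invisibly usable as input to all
#'   downstream functions).
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(RECORD_COLS, names(records))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records$patient_id <- as.character(records$patient_id)
  records$sensor <- as.character(records$sensor)
  bad_sensor <- !records$sensor %in% SENSOR_LEVELS
  if (any(bad_sensor)) {
    stop("unknown sensor label(s) in row(s) ",
         paste(utils::head(which(bad_sensor), 5L), collapse = ", "),
         " (expected DHF or REC)", call. = FALSE)
  }
  if (!is.numeric(records$time_min) || !is.numeric(records$temp_c)) {
    stop("time_min and temp_c must be numeric", call. = FALSE)
  }
  bad_temp <- !is.finite(records$temp_c)
  if (any(bad_temp)) {
    stop("non-finite temperature in row(s) ",
         paste(utils::head(which(bad_temp), 5L), collapse = ", "),
         call. = FALSE)
  }
  bad_time <- !is.finite(records$time_min) | records$time_min < 0
  if (any(bad_time)) {
    stop("negative or non-finite time_min in row(s) ",
         paste(utils::head(which(bad_time), 5L), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(records$patient_id, records$sensor, records$time_min, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    stop("duplicated (patient_id, sensor, time_min) key in row(s) ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  ord <- order(records$patient_id, records$sensor, records$time_min)
  records <- records[ord, RECORD_COLS, drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Read long-format temperature records from delimited text
#'
#' Reads a delimited file with columns `patient_id,sensor,time_min,temp_c`
#' (one row per reading), validates it with [validate_records()] and returns
#' it grouped and sorted by (patient, sensor, time). Malformed numeric fields
#' are reported with their row number.
#'
#' @param path path to the delimited file.
#' @param sep field separator (default `","`).
#' @return A validated data frame of measurement records.
#' @export
read_records <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE)
  missing_cols <- setdiff(RECORD_COLS, names(raw))
  if (length(missing_cols)) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(x, what) {
    suppressWarnings(val <- as.numeric(x))
    bad <- is.na(val) & !is.na(x)
    if (any(bad)) {
      stop("non-numeric ", what, " in data row(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "),
           " of ", path, call. = FALSE)
    }
    val
  }
  rec <- data.frame(
    patient_id = raw$patient_id,
    sensor = raw$sensor,
    time_min = parse_num(raw$time_min, "time_min"),
    temp_c = parse_num(raw$temp_c, "temp_c"),
    stringsAsFactors = FALSE
  )
  validate_records(rec)
}

#' Write temperature records as delimited text
#'
#' Serializes records in the long CSV format read by [read_records()].
#' Temperatures are written with enough decimals (>= 3) that the cleaning
#' thresholds remain unambiguous after a round trip.
#'
#' @param records validated record data frame.
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, sep = ",") {
  if (nrow(records)) records <- validate_records(records)
  out <- data.frame(
    patient_id = as.character(records$patient_id),
    sensor = as.character(records$sensor),
    time_min = format(records$time_min, trim = TRUE, scientific = FALSE),
    temp_c = formatC(records$temp_c, format = "fg", digits = 15),
    stringsAsFactors = FALSE
  )
  if (!nrow(records)) {
    out <- out[0, RECORD_COLS, drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = sep, quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write records to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Analysis run configuration
#'
#' Bundles the tunable constants of the pipeline: cleaning rules, error-grid
#' thresholds, the limits-of-agreement multiplier and confidence level, and
#' the proportional-bias trend method.
#'
#' @param cleaning a [cleaning_config()].
#' @param grid a [grid_thresholds()].
#' @param loa_z standard-normal multiplier for the limits of agreement
#'   (default 1.959964, the conventional 95% value).
#' @param conf_level confidence level for all interval estimates.
#' @param trend_method `"cluster_robust_ols"` (cluster-robust regression of
#'   difference on pair mean) or `"mixed_random_intercept"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cleaning = cleaning_config(),
                       grid = grid_thresholds(),
                       loa_z = 1.959964,
                       conf_level = 0.95,
                       trend_method = c("cluster_robust_ols",
                                        "mixed_random_intercept")) {
  trend_method <- match.arg(trend_method)
  stopifnot(is.numeric(loa_z), length(loa_z) == 1L, loa_z > 0,
            is.numeric(conf_level), length(conf_level) == 1L,
            conf_level > 0, conf_level < 1)
  structure(list(cleaning = cleaning, grid = grid, loa_z = loa_z,
                 conf_level = conf_level, trend_method = trend_method),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Any subset of the keys may be present; absent keys keep their defaults.
#' Recognised keys: `cleaning:` (`discard_first_n`, `jump_threshold_c`,
#' `floor_c`, `interval_min`, `pairing_tolerance_min`), `grid:`
#' (`tolerance_c`, `hypo_c`, `hyper_c`), `loa_z`, `conf_level`,
#' `trend_method`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  cl <- do.call(cleaning_config, y$cleaning %||% list())
  gr <- do.call(grid_thresholds, y$grid %||% list())
  args <- list(cleaning = cl, grid = gr)
  for (k in c("loa_z", "conf_level", "trend_method")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
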