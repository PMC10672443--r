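#' Configuration of the synthetic paired-temperature generator
#'
#' Defines a generative model of an intraoperative paired-monitoring cohort
#' on a 2-min recording grid. Each patient has a latent core trajectory
#' (individual starting temperature, a piecewise-linear drift emulating
#' early redistribution cooling followed by a plateau under active warming,
#' and smooth AR(1) fluctuations). The reference sensor reads the core plus
#' white noise; the test (DHF) sensor adds a constant offset, an optional
#' proportional bias anchored at a reference temperature, a per-patient
#' offset, and its own white noise. Occasional probe-dislocation artifacts
#' (a sustained jump or a sub-30 C excursion corrupting the tail of a
#' stream) can be injected.
#'
#' The per-patient number of retained pairs is drawn from a discretized
#' log-normal (clipped at `min_pairs`) whose defaults give a median of about
#' 26 pairs with quartiles near 16 and 39, so a 51-patient cohort carries
#' about 1650 pairs in expectation; two extra leading readings per stream
#' are generated to feed the equilibration discard.
#'
#' @param n_patients number of patients (default 51).
#' @param pairs_meanlog,pairs_sdlog log-normal parameters of the per-patient
#'   retained-pair count (defaults `log(26)` and 0.65).
#' @param min_pairs lower clip for the pair count (default 3).
#' @param interval_min recording interval, minutes (default 2).
#' @param core_start_mean,core_start_sd per-patient initial core
#'   temperature, degrees C (defaults 36.7, 0.4).
#' @param drift_knots_min,drift_slopes piecewise-linear core drift: slope
#'   `drift_slopes[k]` (deg C per min) applies from `drift_knots_min[k]`;
#'   defaults: -0.01 C/min for the first 30 min, then plateau.
#' @param ar_coefficient AR(1) coefficient of core fluctuations (default
#'   0.8).
#' @param ar_sd innovation SD of the AR(1) fluctuation, degrees C (default
#'   0.1).
#' @param bias0_c constant DHF offset at the reference temperature, degrees
#'   C (default 0.413).
#' @param bias1 proportional bias: extra DHF offset per degree of core above
#'   `ref_temp_c` (default 0).
#' @param ref_temp_c anchor of the proportional bias (default 36.7).
#' @param sigma_subject_c SD of the per-patient DHF offset (default 0.5).
#' @param sigma_noise_dhf_c,sigma_noise_rec_c white measurement-noise SDs
#'   (defaults 0.15, 0.10).
#' @param p_dislocation per-stream probability of an injected dislocation
#'   artifact (default 0.05).
#' @param equilibration_n extra leading readings per stream (default 2).
#' @param seed integer seed; generation is a pure function of the config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 51L,
                             pairs_meanlog = log(26), pairs_sdlog = 0.65,
                             min_pairs = 3L,
                             interval_min = 2,
                             core_start_mean = 36.7, core_start_sd = 0.4,
                             drift_knots_min = c(0, 30),
                             drift_slopes = c(-0.01, 0),
                             ar_coefficient = 0.8, ar_sd = 0.1,
                             bias0_c = 0.413, bias1 = 0,
                             ref_temp_c = 36.7,
                             sigma_subject_c = 0.5,
                             sigma_noise_dhf_c = 0.15,
                             sigma_noise_rec_c = 0.10,
                             p_dislocation = 0.05,
                             equilibration_n = 2L,
                             seed = 1L) {
  stopifnot(n_patients >= 1, pairs_sdlog >= 0, min_pairs >= 1,
            interval_min > 0, core_start_sd >= 0, ar_sd >= 0,
            abs(ar_coefficient) < 1, sigma_subject_c >= 0,
            sigma_noise_dhf_c >= 0, sigma_noise_rec_c >= 0,
            p_dislocation >= 0, p_dislocation <= 1,
            length(drift_knots_min) == length(drift_slopes),
            equilibration_n >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Study-like generator configuration
#'
#' The default [synthetic_config()] with a chosen seed: 51 patients on a
#' 2-min grid, a median of about 26 retained pairs per patient (quartiles
#' about 16-39, cohort total about 1650 pairs), constant bias 0.413 C and
#' plausible intraoperative variance components.
#'
#' @param seed integer seed.
#' @param ... overrides passed to [synthetic_config()].
#' @return A `synthetic_config`.
#' @export
study_like_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed, ...)
}

# cumulative piecewise-linear drift at times t (minutes)
drift_at <- function(t, knots, slopes) {
  out <- numeric(length(t))
  for (k in seq_along(knots)) {
    upper <- if (k < length(knots)) knots[k + 1] else Inf
    span <- pmax(0, pmin(t, upper) - knots[k])
    out <- out + slopes[k] * span
  }
  out
}

#' Generate a synthetic paired-temperature cohort
#'
#' Draws a cohort from the generative model described in
#' [synthetic_config()] and returns both the records in the long analysis
#' format and a truth record holding every latent quantity, so parameter
#' recovery can be tested end to end.
#'
#' @param cfg a [synthetic_config()].
#' @return A list with `records` (long data frame: `patient_id`, `sensor`,
#'   `time_min`, `temp_c`) and `truth`: the config plus per-patient
#'   `n_pairs`, `core_start`, `subject_offset`, artifact descriptors, and
#'   the implied difference variance components `sigma_b2`
#'   (= `sigma_subject_c^2` plus a proportional-bias contribution) and
#'   `sigma_w2` (= sum of the two noise variances, plus the
#'   proportional-bias share of within-patient core variation).
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  m <- pmax(cfg$min_pairs,
            round(stats::rlnorm(n, cfg$pairs_meanlog, cfg$pairs_sdlog)))
  start <- stats::rnorm(n, cfg$core_start_mean, cfg$core_start_sd)
  offset <- stats::rnorm(n, 0, cfg$sigma_subject_c)

  recs <- vector("list", n)
  artifacts <- vector("list", n)
  for (i in seq_len(n)) {
    L <- m[i] + cfg$equilibration_n
    t <- (seq_len(L) - 1) * cfg$interval_min
    ar <- numeric(L)
    innov <- stats::rnorm(L, 0, cfg$ar_sd)
    stat_sd <- if (cfg$ar_sd > 0) cfg$ar_sd / sqrt(1 - cfg$ar_coefficient^2) else 0
    ar[1] <- stats::rnorm(1, 0, stat_sd)
    for (j in seq_len(L - 1)) ar[j + 1] <- cfg$ar_coefficient * ar[j] + innov[j + 1]
    core <- start[i] + drift_at(t, cfg$drift_knots_min, cfg$drift_slopes) + ar
    rec <- core + stats::rnorm(L, 0, cfg$sigma_noise_rec_c)
    dhf <- core + cfg$bias0_c + cfg$bias1 * (core - cfg$ref_temp_c) +
      offset[i] + stats::rnorm(L, 0, cfg$sigma_noise_dhf_c)

    art <- list()
    for (s in c("DHF", "REC")) {
      if (stats::runif(1) < cfg$p_dislocation && L > cfg$equilibration_n + 2) {
        kind <- sample(c("jump", "floor"), 1)
        at <- sample((cfg$equilibration_n + 2):L, 1)
        idx <- at:L
        if (kind == "jump") {
          # size the sustained shift so the realized step from the previous
          # observed reading is exactly the drawn magnitude (> 1.2 C), i.e.
          # the dislocation is always larger than the natural fluctuation
          step <- sample(c(-1, 1), 1) * stats::runif(1, 1.2, 3)
          y <- if (s == "DHF") dhf else rec
          shift <- step - (y[at] - y[at - 1])
          if (s == "DHF") dhf[idx] <- dhf[idx] + shift
          else rec[idx] <- rec[idx] + shift
        } else {
          vals <- stats::runif(length(idx), 25, 29.5)
          if (s == "DHF") dhf[idx] <- vals else rec[idx] <- vals
        }
        art[[s]] <- list(sensor = s, kind = kind, time_min = t[at],
                         index = at)
      }
    }
    artifacts[[i]] <- art
    recs[[i]] <- data.frame(
      patient_id = ids[i],
      sensor = rep(c("DHF", "REC"), each = L),
      time_min = c(t, t),
      temp_c = c(dhf, rec),
      stringsAsFactors = FALSE
    )
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  names(artifacts) <- ids

  # implied components of the paired difference
  # diff = bias0 + offset_i + bias1 * (core - ref) + e_dhf - e_rec
  core_var_within <- if (cfg$ar_sd > 0) {
    (cfg$ar_sd / sqrt(1 - cfg$ar_coefficient^2))^2
  } else 0
  truth <- list(
    config = cfg,
    patient_id = ids,
    n_pairs = m,
    core_start = start,
    subject_offset = offset,
    artifacts = artifacts,
    bias_c = cfg$bias0_c,
    sigma_b2 = cfg$sigma_subject_c^2,
    sigma_w2 = cfg$sigma_noise_dhf_c^2 + cfg$sigma_noise_rec_c^2 +
      cfg$bias1^2 * core_var_within
  )
  list(records = records, truth = truth)
}
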