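#' One-way variance components of paired differences
#'
#' Method-of-moments (ANOVA) decomposition of the device differences into
#' between-subject and within-subject components on a possibly unbalanced
#' design. With subjects i = 1..n contributing m_i differences d_ij
#' (N = sum m_i):
#' \deqn{MSW = \sum_i \sum_j (d_{ij} - \bar d_i)^2 / (N - n)}
#' \deqn{MSB = \sum_i m_i (\bar d_i - \bar d_w)^2 / (n - 1)}
#' with \eqn{\bar d_w} the observation-weighted grand mean,
#' \eqn{m_0 = (N - \sum_i m_i^2 / N)/(n - 1)}, \eqn{\hat\sigma_w^2 = MSW}
#' and \eqn{\hat\sigma_b^2 = \max(0, (MSB - MSW)/m_0)}. The reported bias is
#' by default the unweighted mean of the subject means, so every patient
#' counts equally regardless of monitoring duration.
#'
#' @param pairs paired-observation data frame with columns `patient_id` and
#'   `diff` (see [pair_streams()]).
#' @param bias_weighting `"subject"` (unweighted mean of subject means,
#'   default) or `"observation"` (grand mean over all pairs).
#' @return A list with `bias` (d-bar), `sigma_b2`, `sigma_w2`, `msb`, `msw`,
#'   `m0`, `n` (subjects), `N` (pairs), `m_i` (named per-subject counts),
#'   `subject_means`, `grand_mean_weighted` and `truncated` (logical: was a
#'   negative between-component truncated to zero).
#' @export
variance_components <- function(pairs,
                                bias_weighting = c("subject", "observation")) {
  bias_weighting <- match.arg(bias_weighting)
  stopifnot(is.data.frame(pairs), all(c("patient_id", "diff") %in% names(pairs)))
  d <- pairs$diff
  g <- as.character(pairs$patient_id)
  if (!length(d)) stop("no pairs supplied", call. = FALSE)
  m_i <- tapply(d, g, length)
  n <- length(m_i)
  N <- length(d)
  if (n < 2L) stop("need at least 2 subjects to estimate components",
                   call. = FALSE)
  subj_means <- tapply(d, g, mean)
  d_w <- mean(d)
  msb <- sum(m_i * (subj_means - d_w)^2) / (n - 1)
  if (N > n) {
    msw <- sum((d - subj_means[g])^2) / (N - n)
  } else {
    warning("all subjects contribute a single pair; within-subject variance ",
            "set to 0 (classic Bland-Altman limit)", call. = FALSE)
    msw <- 0
  }
  m0 <- (N - sum(m_i^2) / N) / (n - 1)
  sigma_b2_raw <- (msb - msw) / m0
  truncated <- sigma_b2_raw < 0
  sigma_b2 <- max(0, sigma_b2_raw)
  bias <- if (bias_weighting == "subject") mean(subj_means) else d_w
  list(bias = unname(bias), sigma_b2 = unname(sigma_b2),
       sigma_w2 = unname(msw), msb = unname(msb), msw = unname(msw),
       m0 = unname(m0), n = n, N = N, m_i = m_i,
       subject_means = subj_means, grand_mean_weighted = d_w,
       bias_weighting = bias_weighting, truncated = truncated)
}

# MOVER confidence limits for each limit of agreement, plus its standard
# error, from the ANOVA pieces. B = MSB/m0 and W = (1 - 1/m0) * MSW add up
# to sigma_d^2 (before truncation); chi-square margins on each piece are
# recombined by the square-root-of-summed-squared-margins rule, then folded
# with the t-margin of the bias.
mover_limits <- function(vc, z, conf_level) {
  alpha <- 1 - conf_level
  n <- vc$n; N <- vc$N
  B <- vc$msb / vc$m0
  W <- (1 - 1 / vc$m0) * vc$msw
  sigma_d2 <- vc$sigma_b2 + vc$sigma_w2
  sigma_d <- sqrt(sigma_d2)
  m_h <- 1 / mean(1 / vc$m_i)            # harmonic mean of the m_i
  var_dbar <- vc$sigma_b2 / n + vc$sigma_w2 / (n * m_h)
  se_dbar <- sqrt(var_dbar)
  t_q <- stats::qt(1 - alpha / 2, df = n - 1)
  bias_margin <- t_q * se_dbar

  df_b <- n - 1
  df_w <- N - n
  lm_b <- B * (1 - df_b / stats::qchisq(1 - alpha / 2, df_b))
  um_b <- B * (df_b / stats::qchisq(alpha / 2, df_b) - 1)
  if (df_w > 0 && W > 0) {
    lm_w <- W * (1 - df_w / stats::qchisq(1 - alpha / 2, df_w))
    um_w <- W * (df_w / stats::qchisq(alpha / 2, df_w) - 1)
  } else {
    lm_w <- um_w <- 0
  }
  var_lo <- max(sigma_d2 - sqrt(lm_b^2 + lm_w^2), 0)
  var_hi <- sigma_d2 + sqrt(um_b^2 + um_w^2)
  lme_sd <- z * (sigma_d - sqrt(var_lo))   # downward margin of z*sigma_d
  ume_sd <- z * (sqrt(var_hi) - sigma_d)   # upward margin

  # delta-method SE of each limit
  var_sigma_d2 <- 2 * B^2 / df_b + if (df_w > 0) 2 * W^2 / df_w else 0
  var_sigma_d <- if (sigma_d2 > 0) var_sigma_d2 / (4 * sigma_d2) else 0
  se_loa <- sqrt(var_dbar + z^2 * var_sigma_d)

  loa_upper <- vc$bias + z * sigma_d
  loa_lower <- vc$bias - z * sigma_d
  list(
    sigma_d = sigma_d,
    se_dbar = se_dbar,
    se_loa = se_loa,
    ci_bias = c(vc$bias - bias_margin, vc$bias + bias_margin),
    ci_loa_upper = c(loa_upper - sqrt(bias_margin^2 + lme_sd^2),
                     loa_upper + sqrt(bias_margin^2 + ume_sd^2)),
    ci_loa_lower = c(loa_lower - sqrt(bias_margin^2 + ume_sd^2),
                     loa_lower + sqrt(bias_margin^2 + lme_sd^2)),
    loa_lower = loa_lower, loa_upper = loa_upper
  )
}

#' Repeated-measures Bland-Altman limits of agreement (Zou's method)
#'
#' Fits the agreement model for paired measurements with multiple
#' observations per subject: bias (mean difference), between- and
#' within-subject variance components of the difference, 95% limits of
#' agreement \eqn{\bar d \pm z \hat\sigma_d} with
#' \eqn{\hat\sigma_d^2 = \hat\sigma_b^2 + \hat\sigma_w^2}, MOVER confidence
#' intervals and a standard error for each limit, the proportion of
#' differences within the clinical tolerance, and a proportional-bias trend
#' test of difference against pair mean (see [trend_test()]).
#'
#' With one pair per subject the fit reduces exactly to the classic
#' Bland-Altman analysis (mean difference \eqn{\pm z} times the SD of the n
#' differences).
#'
#' @param pairs paired-observation data frame with columns `patient_id`,
#'   `t_dhf`, `t_rec`, `diff`, `pair_mean` (as produced by [pair_streams()]
#'   or [clean_cohort()]); `diff` and `pair_mean` are recomputed from the
#'   temperatures if absent.
#' @param z limits-of-agreement multiplier (default 1.959964).
#' @param conf_level confidence level of all intervals (default 0.95).
#' @param tolerance_c clinically acceptable absolute difference in degrees C
#'   (default 0.5); the comparison is inclusive.
#' @param trend_method method for the trend test, or `"none"` to skip it.
#' @param bias_weighting see [variance_components()].
#' @return An object of class `zou_loa`; see [summary.zou_loa()]. Key
#'   elements: `bias_c`, `sigma_b2`, `sigma_w2`, `sigma_d`, `loa_lower_c`,
#'   `loa_upper_c`, `loa_halfwidth_c`, `se_loa_c`, `ci_bias`,
#'   `ci_loa_lower`, `ci_loa_upper`, `prop_within_tolerance`, `acceptable`,
#'   `trend`, `n_subjects`, `n_pairs`, `m_i`.
#' @examples
#' set.seed(1)
#' cohort <- generate_cohort(synthetic_config(n_patients = 20, seed = 1))
#' pairs <- clean_cohort(cohort$records)$pairs
#' fit <- zou_loa(pairs)
#' fit
#' coef(fit)
#' confint(fit)
#' @export
zou_loa <- function(pairs, z = 1.959964, conf_level = 0.95,
                    tolerance_c = 0.5,
                    trend_method = c("cluster_robust_ols",
                                     "mixed_random_intercept", "none"),
                    bias_weighting = c("subject", "observation")) {
  trend_method <- match.arg(trend_method)
  stopifnot(z > 0, conf_level > 0, conf_level < 1, tolerance_c > 0)
  pairs <- as.data.frame(pairs)
  if (is.null(pairs$diff)) pairs$diff <- pairs$t_dhf - pairs$t_rec
  if (is.null(pairs$pair_mean) && !is.null(pairs$t_dhf)) {
    pairs$pair_mean <- (pairs$t_dhf + pairs$t_rec) / 2
  }
  vc <- variance_components(pairs, bias_weighting = bias_weighting)
  mv <- mover_limits(vc, z, conf_level)
  prop <- proportion_within(pairs, tolerance_c)
  trend <- if (trend_method != "none" && !is.null(pairs$pair_mean) &&
               vc$n >= 3L && stats::var(pairs$pair_mean) > 0) {
    trend_test(pairs, method = trend_method)
  } else NULL
  structure(list(
    n_subjects = vc$n, n_pairs = vc$N, m_i = vc$m_i,
    bias_c = vc$bias, sigma_b2 = vc$sigma_b2, sigma_w2 = vc$sigma_w2,
    sigma_d = mv$sigma_d,
    loa_lower_c = mv$loa_lower, loa_upper_c = mv$loa_upper,
    loa_halfwidth_c = z * mv$sigma_d,
    se_bias_c = mv$se_dbar, se_loa_c = mv$se_loa,
    ci_bias = mv$ci_bias, ci_loa_lower = mv$ci_loa_lower,
    ci_loa_upper = mv$ci_loa_upper,
    prop_within_tolerance = prop,
    tolerance_c = tolerance_c,
    acceptable = (mv$loa_lower >= -tolerance_c && mv$loa_upper <= tolerance_c),
    degenerate = mv$sigma_d == 0,
    truncated = vc$truncated,
    z = z, conf_level = conf_level,
    bias_weighting = vc$bias_weighting,
    trend = trend,
    pairs = pairs,
    call = match.call()
  ), class = "zou_loa")
}

#' Proportion of differences within a clinical tolerance
#'
#' Fraction of paired differences with `|diff| <= tolerance_c` (inclusive).
#'
#' @param pairs paired-observation data frame with a `diff` column.
#' @param tolerance_c tolerance in degrees C (default 0.5).
#' @return A fraction in `[0, 1]`.
#' @export
proportion_within <- function(pairs, tolerance_c = 0.5) {
  d <- pairs$diff
  if (!length(d)) stop("no pairs supplied", call. = FALSE)
  mean(abs(d) <= tolerance_c)
}

#' Proportional-bias trend test
#'
#' Regression of the paired difference on the pair mean. Because each patient
#' contributes many correlated pairs, the default inference uses
#' cluster-robust (HC1) standard errors by patient with a t reference on
#' (number of patients - 1) degrees of freedom; the alternative fits a
#' random-intercept mixed model with Satterthwaite degrees of freedom.
#'
#' @param pairs paired-observation data frame with `patient_id`, `diff`,
#'   `pair_mean`.
#' @param method `"cluster_robust_ols"` or `"mixed_random_intercept"`.
#' @return A list of class `loa_trend` with `slope` (degrees C per degree C),
#'   `intercept`, `se_slope`, `p_value` (two-sided) and `method`.
#' @export
trend_test <- function(pairs, method = c("cluster_robust_ols",
                                         "mixed_random_intercept")) {
  method <- match.arg(method)
  stopifnot(all(c("patient_id", "diff", "pair_mean") %in% names(pairs)))
  g <- factor(pairs$patient_id)
  if (nlevels(g) < 3L) stop("trend test needs at least 3 subjects",
                            call. = FALSE)
  if (stats::var(pairs$pair_mean) == 0) {
    stop("pair_mean is constant; slope not identifiable", call. = FALSE)
  }
  if (method == "cluster_robust_ols") {
    fit <- stats::lm(diff ~ pair_mean, data = pairs)
    V <- sandwich::vcovCL(fit, cluster = g, type = "HC1")
    est <- stats::coef(fit)
    se <- sqrt(diag(V))
    df <- nlevels(g) - 1L
    tval <- est[["pair_mean"]] / se[["pair_mean"]]
    p <- 2 * stats::pt(-abs(tval), df = df)
    out <- list(slope = est[["pair_mean"]], intercept = est[["(Intercept)"]],
                se_slope = se[["pair_mean"]], p_value = p, method = method)
  } else {
    fit <- lmerTest::lmer(diff ~ pair_mean + (1 | patient_id),
                          data = pairs, REML = TRUE)
    co <- stats::coef(summary(fit))
    out <- list(slope = co["pair_mean", "Estimate"],
                intercept = co["(Intercept)", "Estimate"],
                se_slope = co["pair_mean", "Std. Error"],
                p_value = co["pair_mean", "Pr(>|t|)"],
                method = method)
  }
  class(out) <- "loa_trend"
  out
}

#' Aggregated Bland-Altman plot data
#'
#' Bins pairs to a rounding grid on both axes and attaches multiplicity
#' counts (many intraoperative readings repeat to instrument resolution), so
#' plotted point sizes can encode the number of observations. Also returns
#' the reference lines of the standard display: zero, the clinical tolerance
#' band, the bias and both limits of agreement, plus the fitted trend line.
#'
#' @param fit a [zou_loa()] fit.
#' @param rounding grid step in degrees C (default 0.1).
#' @return A list with `points` (data frame `pair_mean`, `diff`, `count`),
#'   `lines` (named vector: `zero`, `tol_lower`, `tol_upper`, `bias`,
#'   `loa_lower`, `loa_upper`) and `trend` (slope/intercept or `NULL`).
#' @export
ba_plot_data <- function(fit, rounding = 0.1) {
  stopifnot(inherits(fit, "zou_loa"), rounding > 0)
  pairs <- fit$pairs
  gx <- round(pairs$pair_mean / rounding) * rounding
  gy <- round(pairs$diff / rounding) * rounding
  key <- paste(gx, gy, sep = "\r")
  agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
  parts <- strsplit(agg$key, "\r", fixed = TRUE)
  points <- data.frame(
    pair_mean = as.numeric(vapply(parts, `[[`, "", 1L)),
    diff = as.numeric(vapply(parts, `[[`, "", 2L)),
    count = agg$Freq
  )
  points <- points[order(points$pair_mean, points$diff), , drop = FALSE]
  rownames(points) <- NULL
  lines <- c(zero = 0, tol_lower = -fit$tolerance_c,
             tol_upper = fit$tolerance_c, bias = fit$bias_c,
             loa_lower = fit$loa_lower_c, loa_upper = fit$loa_upper_c)
  trend <- if (!is.null(fit$trend)) {
    c(intercept = fit$trend$intercept, slope = fit$trend$slope)
  } else NULL
  list(points = points, lines = lines, trend = trend)
}

#' @export
print.zou_loa <- function(x, digits = 3, ...) {
  cat("Repeated-measures Bland-Altman limits of agreement (Zou)\n")
  cat(sprintf("  %d subjects, %d pairs (per-subject median %s)\n",
              x$n_subjects, x$n_pairs, format(stats::median(x$m_i))))
  cat(sprintf("  Bias: %s C   LoA: [%s, %s] C   SE(LoA): %s C\n",
              format(round(x$bias_c, digits)),
              format(round(x$loa_lower_c, digits)),
              format(round(x$loa_upper_c, digits)),
              format(round(x$se_loa_c, digits))))
  cat(sprintf("  |diff| <= %s C: %.2f%%   LoA within tolerance: %s\n",
              format(x$tolerance_c), 100 * x$prop_within_tolerance,
              if (x$acceptable) "yes" else "no"))
  invisible(x)
}

#' @export
coef.zou_loa <- function(object, ...) {
  c(bias = object$bias_c, loa_lower = object$loa_lower_c,
    loa_upper = object$loa_upper_c)
}

#' @export
confint.zou_loa <- function(object, parm, level, ...) {
  out <- rbind(bias = object$ci_bias,
               loa_lower = object$ci_loa_lower,
               loa_upper = object$ci_loa_upper)
  alpha <- 1 - object$conf_level
  colnames(out) <- paste0(format(100 * c(alpha / 2, 1 - alpha / 2),
                                 trim = TRUE), " %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
residuals.zou_loa <- function(object, ...) {
  object$pairs$diff - object$bias_c
}

#' Summary of a repeated-measures agreement fit
#'
#' @param object a [zou_loa()] fit.
#' @param ... unused.
#' @return The fit, invisibly, after printing variance components, limits
#'   with confidence intervals, the acceptability assessment and the trend
#'   test.
#' @export
summary.zou_loa <- function(object, ...) {
  x <- object
  print(x)
  cat(sprintf("  Variance components: sigma_b2 = %.4f, sigma_w2 = %.4f, sigma_d = %.4f C\n",
              x$sigma_b2, x$sigma_w2, x$sigma_d))
  ci <- confint(x)
  cat(sprintf("  %g%% CI bias:      [%.3f, %.3f]\n", 100 * x$conf_level,
              ci[1, 1], ci[1, 2]))
  cat(sprintf("  %g%% CI lower LoA: [%.3f, %.3f]\n", 100 * x$conf_level,
              ci[2, 1], ci[2, 2]))
  cat(sprintf("  %g%% CI upper LoA: [%.3f, %.3f]\n", 100 * x$conf_level,
              ci[3, 1], ci[3, 2]))
  if (!is.null(x$trend)) {
    cat(sprintf("  Trend (diff ~ pair mean, %s): slope %.3f C/C, p = %.3g\n",
                x$trend$method, x$trend$slope, x$trend$p_value))
  }
  invisible(x)
}

#' Bland-Altman plot of a fitted agreement model
#'
#' Draws the difference-versus-mean scatter with point sizes scaled to the
#' number of coincident observations, the zero and tolerance reference lines,
#' the bias, both limits of agreement and the fitted linear trend.
#'
#' @param x a [zou_loa()] fit.
#' @param rounding binning step for coincident points (degrees C).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.zou_loa <- function(x, rounding = 0.1, ...) {
  pd <- ba_plot_data(x, rounding)
  pts <- pd$points
  cex <- 0.6 + 1.4 * sqrt(pts$count / max(pts$count))
  ylim <- range(c(pts$diff, pd$lines))
  graphics::plot(pts$pair_mean, pts$diff, cex = cex, pch = 21,
                 bg = "grey70",
                 xlab = "Pair mean temperature (C)",
                 ylab = "Difference DHF - reference (C)",
                 ylim = ylim + c(-0.1, 0.1), ...)
  graphics::abline(h = pd$lines[["zero"]], lty = 2, col = "grey50")
  graphics::abline(h = pd$lines[c("tol_lower", "tol_upper")], lty = 3,
                   col = "grey50")
  graphics::abline(h = pd$lines[["bias"]], col = "darkorange", lwd = 2)
  graphics::abline(h = pd$lines[c("loa_lower", "loa_upper")],
                   col = "darkorange", lty = 2)
  if (!is.null(pd$trend)) {
    graphics::abline(a = pd$trend[["intercept"]], b = pd$trend[["slope"]],
                     col = "steelblue", lwd = 2)
  }
  invisible(x)
}

#' @export
print.loa_trend <- function(x, ...) {
  cat(sprintf("Trend of difference on pair mean (%s)\n", x$method))
  cat(sprintf("  slope = %.4f C/C (SE %.4f), intercept = %.4f, p = %.3g\n",
              x$slope, x$se_slope, x$intercept, x$p_value))
  invisible(x)
}
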