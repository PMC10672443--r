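#' Standard error of a 95% limit of agreement, one pair per subject
#'
#' Exact precision formula for the classic Bland-Altman design with a single
#' difference per subject:
#' \deqn{SE(LoA) = \sigma_d \sqrt{1/n + z^2 / (2(n-1))}}
#' where \eqn{\sigma_d} is the standard deviation of a difference. (The
#' cruder \eqn{\sqrt{3\sigma_d^2/n}} approximation is deliberately not used:
#' it shifts the required n.)
#'
#' @param n number of subjects (>= 2).
#' @param sigma_d SD of a single difference, degrees C.
#' @param z limits-of-agreement multiplier.
#' @return SE of each limit of agreement in degrees C (vectorized over `n`).
#' @export
se_loa_single <- function(n, sigma_d, z = 1.959964) {
  stopifnot(sigma_d >= 0, z > 0)
  if (any(n < 2)) stop("need n >= 2 subjects", call. = FALSE)
  sigma_d * sqrt(1 / n + z^2 / (2 * (n - 1)))
}

#' Subjects needed for a target limits-of-agreement precision (single pair)
#'
#' Smallest integer n with `se_loa_single(n) <= target_se`, found by exact
#' search over n (an analytic bound caps the search; exhaustive search
#' avoids rounding off-by-one).
#'
#' @param sigma_d SD of a single difference, degrees C (planning value).
#' @param target_se required SE of each limit, degrees C.
#' @param z limits-of-agreement multiplier.
#' @return A list with `n` (required subjects) and `achieved_se`.
#' @examples
#' n_for_target_se(sigma_d = 0.25, target_se = 0.05)$n  # 74
#' @export
n_for_target_se <- function(sigma_d, target_se, z = 1.959964) {
  stopifnot(sigma_d > 0, target_se > 0)
  if (se_loa_single(2, sigma_d, z) <= target_se) {
    return(list(n = 2L, achieved_se = se_loa_single(2, sigma_d, z)))
  }
  # SE^2 <= sigma^2 (1 + z^2) / (n - 1), so n - 1 <= sigma^2 (1+z^2)/target^2
  n_max <- ceiling(sigma_d^2 * (1 + z^2) / target_se^2) + 2
  for (n in 3:n_max) {
    if (se_loa_single(n, sigma_d, z) <= target_se) {
      return(list(n = as.integer(n),
                  achieved_se = se_loa_single(n, sigma_d, z)))
    }
  }
  stop("target SE unreachable within search bound", call. = FALSE)
}

#' Standard error of a limit of agreement with repeated measurements
#'
#' Planning-stage SE of each limit under the one-way variance structure with
#' n subjects and m differences each:
#' \deqn{SE^2 = Var(\bar d) + z^2 Var(\hat\sigma_d)}
#' with \eqn{Var(\bar d) = (\sigma_b^2 + \sigma_w^2/m)/n} and
#' \eqn{Var(\hat\sigma_d)} from the delta method on the chi-square variances
#' of the two ANOVA pieces (degrees of freedom n - 1 between, n(m - 1)
#' within). With m = 1 and the whole difference variance between subjects it
#' reduces exactly to [se_loa_single()].
#'
#' @param n subjects (>= 2).
#' @param m planned differences per subject (>= 1).
#' @param sigma_b2 between-subject variance of the difference (deg C^2).
#' @param sigma_w2 within-subject variance of the difference (deg C^2).
#' @param z limits-of-agreement multiplier.
#' @return SE of each limit in degrees C (vectorized over `n`).
#' @export
se_loa_repeated <- function(n, m, sigma_b2, sigma_w2, z = 1.959964) {
  stopifnot(sigma_b2 >= 0, sigma_w2 >= 0, m >= 1, z > 0)
  if (any(n < 2)) stop("need n >= 2 subjects", call. = FALSE)
  if (m == 1 && sigma_w2 > 0) {
    stop("with m = 1 the within-subject component is inestimable; fold it ",
         "into sigma_b2 (classic single-measurement design)", call. = FALSE)
  }
  sigma_d2 <- sigma_b2 + sigma_w2
  var_dbar <- (sigma_b2 + sigma_w2 / m) / n
  # ANOVA pieces: B-hat = MSB/m estimates sigma_b^2 + sigma_w^2/m with
  # df n - 1; W contribution (1 - 1/m) * MSW with df n(m - 1)
  Bexp <- sigma_b2 + sigma_w2 / m
  Wexp <- (1 - 1 / m) * sigma_w2
  var_sigma_d2 <- 2 * Bexp^2 / (n - 1) +
    if (m > 1) 2 * Wexp^2 / (n * (m - 1)) else 0
  var_sigma_d <- if (sigma_d2 > 0) var_sigma_d2 / (4 * sigma_d2) else 0
  sqrt(var_dbar + z^2 * var_sigma_d)
}

#' Subjects needed for target precision with repeated measurements
#'
#' Smallest integer n with `se_loa_repeated(n, m, ...) <= target_se`, by
#' exact search. This is the design inversion used to recompute a required
#' sample size once pilot estimates of the variance components are
#' available.
#'
#' @param m planned differences per subject.
#' @param sigma_b2,sigma_w2 planning variance components (deg C^2).
#' @param target_se required SE of each limit, degrees C.
#' @param z limits-of-agreement multiplier.
#' @return A list with `n` and `achieved_se`.
#' @export
n_for_target_se_repeated <- function(m, sigma_b2, sigma_w2, target_se,
                                     z = 1.959964) {
  stopifnot(target_se > 0)
  f <- function(n) se_loa_repeated(n, m, sigma_b2, sigma_w2, z)
  if (f(2) <= target_se) return(list(n = 2L, achieved_se = f(2)))
  sigma_d2 <- sigma_b2 + sigma_w2
  n_max <- ceiling(sigma_d2 * (1 + z^2) / target_se^2) + 2
  for (n in 3:n_max) {
    if (f(n) <= target_se) {
      return(list(n = as.integer(n), achieved_se = f(n)))
    }
  }
  stop("target SE unreachable within search bound", call. = FALSE)
}
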