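test_that("variance components match hand ANOVA on tiny designs", {
  # all differences identical: everything collapses to the bias
  flat <- variance_components(make_pairs(list(rep(0.4, 3), rep(0.4, 2))))
  expect_equal(flat$bias, 0.4)
  expect_equal(flat$sigma_b2, 0)
  expect_equal(flat$sigma_w2, 0)

  # 2 subjects x 2 pairs, diffs {0,0} and {1,1}: subject means 0 and 1,
  # weighted grand mean 0.5, MSB = (2*0.25 + 2*0.25)/1 = 1, MSW = 0,
  # m0 = (4 - 8/4)/1 = 2, sigma_b2 = 1/2 -- the sample variance of the
  # subject means, as it must be when sigma_w = 0
  vc <- variance_components(make_pairs(list(c(0, 0), c(1, 1))))
  expect_equal(vc$bias, 0.5)
  expect_equal(vc$grand_mean_weighted, 0.5)
  expect_equal(vc$msb, 1)
  expect_equal(vc$sigma_w2, 0)
  expect_equal(vc$m0, 2)
  expect_equal(vc$sigma_b2, 0.5)
})

test_that("components equal a REML mixed-model fit on balanced designs", {
  set.seed(31)
  for (k in 1:4) {
    n <- sample(8:15, 1); m <- sample(4:8, 1)
    pairs <- simulate_diffs(n, m, bias = 0.4, sigma_b = 0.6, sigma_w = 0.3)
    vc <- variance_components(pairs)
    fit <- lme4::lmer(diff ~ 1 + (1 | patient_id), data = pairs, REML = TRUE)
    v <- as.data.frame(lme4::VarCorr(fit))$vcov
    expect_equal(vc$sigma_b2, v[1], tolerance = 1e-6)
    expect_equal(vc$sigma_w2, v[2], tolerance = 1e-6)
    expect_equal(vc$bias, unname(lme4::fixef(fit))[1], tolerance = 1e-6)
  }
})

test_that("negative between-subject estimates truncate to zero", {
  # subject means nearly equal but large within spread -> MSB < MSW
  pairs <- make_pairs(list(c(-1, 1), c(1, -1), c(-1, 1)))
  vc <- variance_components(pairs)
  expect_true(vc$truncated)
  expect_equal(vc$sigma_b2, 0)
  expect_gt(vc$sigma_w2, 0)
  fit <- zou_loa(pairs, trend_method = "none")
  expect_equal(fit$sigma_d, sqrt(vc$sigma_w2))
})

test_that("one pair per subject reproduces classic Bland-Altman exactly", {
  set.seed(41)
  for (k in 1:100) {
    n <- sample(5:60, 1)
    d <- rnorm(n, 0.3, 0.6)
    pairs <- make_pairs(as.list(d))
    fit <- suppressWarnings(zou_loa(pairs, trend_method = "none"))
    expect_equal(fit$bias_c, mean(d))
    expect_equal(fit$loa_upper_c, mean(d) + 1.959964 * sd(d))
    expect_equal(fit$loa_lower_c, mean(d) - 1.959964 * sd(d))
    expect_equal(fit$se_loa_c, se_loa_single(n, sd(d)))
  }
})

test_that("zero-variance differences give degenerate limits equal to the bias", {
  fit <- zou_loa(make_pairs(list(rep(0.4, 4), rep(0.4, 4))),
                 trend_method = "none")
  expect_true(fit$degenerate)
  expect_equal(fit$loa_lower_c, 0.4)
  expect_equal(fit$loa_upper_c, 0.4)
  expect_equal(fit$loa_halfwidth_c, 0)
})

test_that("fit invariants hold on a simulated cohort", {
  set.seed(51)
  pairs <- simulate_diffs(30, 10, bias = 0.4, sigma_b = 0.5, sigma_w = 0.25)
  fit <- zou_loa(pairs, trend_method = "none")
  expect_equal(fit$loa_upper_c - fit$loa_lower_c, 2 * fit$loa_halfwidth_c)
  expect_equal((fit$loa_upper_c + fit$loa_lower_c) / 2, fit$bias_c)
  expect_equal(fit$sigma_d^2, fit$sigma_b2 + fit$sigma_w2)
  expect_true(fit$ci_loa_upper[1] < fit$loa_upper_c &&
              fit$loa_upper_c < fit$ci_loa_upper[2])
  expect_true(fit$ci_loa_lower[1] < fit$loa_lower_c &&
              fit$loa_lower_c < fit$ci_loa_lower[2])
  co <- coef(fit)
  expect_named(co, c("bias", "loa_lower", "loa_upper"))
  ci <- confint(fit)
  expect_equal(dim(ci), c(3L, 2L))
  expect_equal(mean(residuals(fit)), mean(pairs$diff) - fit$bias_c)
})

test_that("se_loa decreases with the number of subjects", {
  ses <- vapply(c(10, 50, 200), function(n) {
    set.seed(61)
    # noiseless expectation: use the planning formula on fixed components
    se_loa_repeated(n, 10, 0.25, 0.0625)
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("proportion within tolerance is inclusive at the boundary", {
  expect_equal(proportion_within(data.frame(diff = c(0.1, -0.3, 0.49))), 1)
  expect_equal(proportion_within(data.frame(diff = c(0.6, 0.4))), 0.5)
  expect_equal(proportion_within(data.frame(diff = rep(0.5, 7))), 1)
  expect_error(proportion_within(data.frame(diff = numeric(0))), "no pairs")
})

test_that("trend test recovers an exact linear relation and validates input", {
  pm <- rep(seq(35, 39, length.out = 8), 4)
  pairs <- data.frame(patient_id = rep(sprintf("S%d", 1:4), each = 8),
                      pair_mean = pm, diff = 0.2 + 0.3 * pm)
  # noise-free data: lm/sandwich warn about a perfect fit
  tr <- suppressWarnings(trend_test(pairs))
  expect_equal(tr$slope, 0.3, tolerance = 1e-10)
  expect_equal(tr$intercept, 0.2, tolerance = 1e-8)
  # zero-residual data makes the mixed fit warn about singularity
  tr2 <- suppressWarnings(trend_test(pairs, method = "mixed_random_intercept"))
  expect_equal(tr2$slope, 0.3, tolerance = 1e-6)

  expect_error(trend_test(transform(pairs, pair_mean = 36.5)),
               "constant|identifiable")
  expect_error(trend_test(pairs[pairs$patient_id %in% c("S1", "S2"), ]),
               "at least 3 subjects")
})

test_that("plot data aggregates coincident pairs and carries reference lines", {
  pairs <- make_pairs(list(c(0.4, 0.4), c(0.1)))
  fit <- zou_loa(pairs, trend_method = "none")
  pd <- ba_plot_data(fit)
  expect_equal(sum(pd$points$count), 3L)
  expect_equal(max(pd$points$count), 2L)   # the two identical pairs merge
  expect_named(pd$lines, c("zero", "tol_lower", "tol_upper", "bias",
                           "loa_lower", "loa_upper"))
  expect_equal(pd$lines[["bias"]], fit$bias_c)

  distinct <- make_pairs(list(c(0.1, 0.3, -0.2)))
  suppressWarnings(fit2 <- zou_loa(make_pairs(list(c(0.1, 0.3), c(-0.2, 0))),
                                   trend_method = "none"))
  pd2 <- ba_plot_data(fit2)
  expect_true(all(pd2$points$count == 1L))
  # plot method runs without error on a throwaway device
  tf <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tf); on.exit(grDevices::dev.off(), add = TRUE)
  expect_no_error(plot(fit))
})
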