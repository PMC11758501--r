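test_that("logistic_prob matches the printed scenario-3 row and reduces correctly", {
  g <- bench_grid()
  cf <- s3_coeffs()
  expect_equal(round(logistic_prob(cf, g, 5), 2), 0.62)
  expect_equal(round(logistic_prob(cf, g, 1:5), 2),
               c(0.00, 0.07, 0.24, 0.45, 0.62))
  # at the reference dose the slope drops out
  expect_equal(logistic_prob(c(-0.7, 3.1), g, 3), plogis(-0.7))
  # zero covariate coefficients reduce to the no-covariate value
  expect_equal(logistic_prob(cf, g, 4, covariates = c(1.3, -2), gamma = c(0, 0)),
               logistic_prob(cf, g, 4))
  expect_error(logistic_prob(cf, g, 2, covariates = 1, gamma = c(1, 2)),
               "same length")
  expect_error(logistic_prob(cf, g, 6), "dose index")
})

test_that("emax_prob limits and direct evaluation", {
  g <- dose_grid(c(1e-9, 5, 1e9), 5)
  cf <- c(-2, 3, 5)
  expect_equal(emax_prob(cf, g, 1), plogis(-2), tolerance = 1e-6)
  expect_equal(emax_prob(cf, g, 3), plogis(1), tolerance = 1e-6)
  expect_equal(emax_prob(cf, g, 2), plogis(-2 + 3 * 5 / 10))
  expect_error(emax_prob(c(-2, 3, -1), g, 2), "positive")
})

test_that("true_pmtd matches a brute-force scan and breaks ties upward", {
  g <- bench_grid()
  s3 <- scenario_truth("logistic", g, s3_coeffs())
  expect_equal(true_pmtd(s3), 3)
  # exact tie (dyadic probabilities, equidistant from tau) -> higher dose
  expect_equal(select_dose(c(0.1875, 0.3125), 0.25), 2)
  expect_equal(select_dose(c(0.20, 0.30), 0.25), 2)
  set.seed(42)
  for (i in 1:1000) {
    tr <- scenario_truth("logistic", g, c(rnorm(1, -1, 1.5), runif(1, 0.2, 4)),
                         tau = runif(1, 0.1, 0.4))
    p <- true_prob(tr, 1:5)
    d <- abs(p - tr$tau)
    expect_identical(true_pmtd(tr), max(which(d == min(d))))
  }
})

test_that("marginal_prob: exact reductions and Monte Carlo agreement", {
  g <- bench_grid()
  # gamma = 0: marginal equals conditional to machine precision
  s3 <- scenario_truth("logistic", g, s3_coeffs())
  expect_identical(marginal_prob(s3), true_prob(s3, 1:5))
  # single Bernoulli(0.5) covariate: exact two-point average
  cb <- covariate_spec("binary", probs = 0.5)
  tb <- scenario_truth("logistic", g, s3_coeffs(), gamma = 1.2,
                       covariates = cb)
  expect_equal(marginal_prob(tb, 4),
               0.5 * true_prob(tb, 4, 0) + 0.5 * true_prob(tb, 4, 1),
               tolerance = 1e-12)
  # two correlated normals: quadrature within 3 MC standard errors
  cs <- covariate_spec(c("normal", "normal"),
                       correlation = matrix(c(1, .5, .5, 1), 2))
  tn <- scenario_truth("logistic", g, s3_coeffs(), gamma = c(1, -0.7),
                       covariates = cs)
  set.seed(7)
  X <- gen_covariates(cs, 1e6)
  for (k in c(1, 3, 5)) {
    vals <- plogis(qlogis(true_prob(tn, k, c(0, 0))) +
                     as.numeric(X %*% tn$gamma))
    se <- sd(vals) / sqrt(length(vals))
    expect_lt(abs(marginal_prob(tn, k) - mean(vals)), 3 * se + 1e-6)
  }
})

test_that("calibrate_truth closed form reproduces printed rows (round trip)", {
  g <- bench_grid()
  tr3 <- calibrate_truth(c(0.003, 0.07, 0.24, 0.45, 0.62), "logistic", g)
  expect_equal(round(true_prob(tr3, 1:5), 3)[1], 0.003)
  expect_equal(round(true_prob(tr3, 2:5), 2), c(0.07, 0.24, 0.45, 0.62))
  expect_equal(attr(tr3, "anchors"), c(3L, 4L))
  tr1 <- calibrate_truth(c(0.25, 0.39, 0.46, 0.51, 0.55), "logistic", g)
  expect_equal(round(true_prob(tr1, 1:5), 2), c(0.25, 0.39, 0.46, 0.51, 0.55))
  expect_error(calibrate_truth(c(0.3, 0.2, 0.4, 0.5, 0.6), "logistic", g),
               "increasing")
})

test_that("calibrate_truth with fixed gamma matches targets by independent MC", {
  g <- bench_grid()
  cs <- covariate_spec(c("normal", "binary"))
  targets <- c(0.033, 0.24, 0.47, 0.64, 0.75)
  tr <- calibrate_truth(targets, "logistic", g, fixed_gamma = c(1, 0.8),
                        covariates = cs)
  mc <- marginal_prob(tr, control = list(method = "mc", n_mc = 2e5, seed = 3))
  expect_lt(max(abs(mc - marginal_prob(tr))), 0.005)   # engines agree
  expect_lt(max(abs(marginal_prob(tr) - targets)), 0.05)
})

test_that("emax calibration round-trips a monotone target table", {
  g <- bench_grid()
  targets <- c(0.05, 0.15, 0.25, 0.33, 0.40)
  tr <- calibrate_truth(targets, "emax", g)
  expect_lt(max(abs(true_prob(tr, 1:5) - targets)), 0.01)
  expect_gt(tr$coeffs[3], 0)
})

test_that("pmtd_distribution: point mass without covariates, seed stability", {
  g <- bench_grid()
  s3 <- scenario_truth("logistic", g, s3_coeffs())
  expect_equal(unname(pmtd_distribution(s3, 10)), c(0, 0, 1, 0, 0))
  cs <- covariate_spec("normal")
  tr <- calibrate_truth(c(0.003, 0.07, 0.24, 0.45, 0.62), "logistic", g,
                        fixed_gamma = 1.5, covariates = cs)
  d1 <- pmtd_distribution(tr, 1e5, seed = 11)
  d2 <- pmtd_distribution(tr, 1e5, seed = 12)
  expect_equal(sum(d1), 1)
  se <- sqrt(d1 * (1 - d1) / 1e5)
  expect_true(all(abs(d1 - d2) <= 3 * (se + sqrt(d2 * (1 - d2) / 1e5)) + 1e-9))
})

test_that("probability outputs are monotone in dose for positive slopes", {
  g <- bench_grid()
  set.seed(5)
  for (i in 1:50) {
    p <- logistic_prob(c(rnorm(1), runif(1, 0.1, 4)), g, 1:5)
    expect_true(all(diff(p) > 0) && all(p > 0 & p < 1))
    pe <- emax_prob(c(rnorm(1), runif(1, 0.5, 4), runif(1, 1, 8)), g, 1:5)
    expect_true(all(diff(pe) > 0) && all(pe > 0 & pe < 1))
  }
})
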