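test_that("select_dose: printed geometry, tie rule, brute-force scan", {
  expect_equal(select_dose(c(0.25, 0.39, 0.46, 0.51, 0.55), 0.25), 1)
  expect_equal(select_dose(c(0.20, 0.30), 0.25), 2)
  expect_error(select_dose(numeric(), 0.25), "empty")
  set.seed(8)
  for (i in 1:1000) {
    p <- runif(sample(2:6, 1))
    tau <- runif(1, 0.1, 0.4)
    d <- abs(p - tau)
    expect_identical(select_dose(p, tau), max(which(d == min(d))))
  }
  # row-wise version agrees with the scalar rule
  P <- matrix(runif(300), 60, 5)
  expect_identical(pmtddesign:::select_dose_rows(P, 0.25),
                   apply(P, 1, select_dose, tau = 0.25))
})

test_that("allocate_cohort: shared dose without covariates, pMTD ordering with", {
  g <- bench_grid()
  f0 <- fit_posterior(prior_spec(), tiny_data(12, seed = 1), g)
  a <- allocate_cohort(f0, matrix(0, 3, 0), tau = 0.25)
  expect_length(unique(a), 1)
  # point-mass posterior with positive gamma: the higher-risk patient gets
  # a dose no higher than the lower-risk one
  pp <- point_mass_posterior(qlogis(0.1), log(2), 1.5, g)
  x <- 0.9
  d <- allocate_cohort(pp, matrix(c(x, -x), 2, 1), tau = 0.25)
  expect_lte(d[1], d[2])
  # gamma pinned near zero: allocation equals the covariate-free one
  pr0 <- prior_spec("normal", type = "normal", sigma2 = 1e-10)
  dd <- tiny_data(12, seed = 1, p = 1)
  fg <- fit_posterior(pr0, dd, g, engine = "quadrature",
                      settings = list(nodes = 61, span = 6))
  f00 <- fit_posterior(prior_spec(), dd, g)
  a0 <- allocate_cohort(f00, matrix(0, 4, 0), tau = 0.25)
  ag <- allocate_cohort(fg, matrix(rnorm(4), 4, 1), tau = 0.25)
  expect_identical(ag, a0)
})

test_that("cchange_ratio hits its boundary values {0, 1/n, 1}", {
  g <- bench_grid()
  # "without" model: covariate-free point mass recommending d3 for everyone
  base <- point_mass_posterior(qlogis(0.25), log(1.5), grid = g)
  dd <- trial_data(c(1, 2, 3), c(0, 0, 0), matrix(c(0, 0, 3), 3, 1))
  # identical curves -> ratio 0
  same <- point_mass_posterior(qlogis(0.25), log(1.5), 0, g)
  expect_equal(cchange_ratio(dd, base, same, 0.25), 0)
  # strong covariate flips only the x = 3 patient -> 1/3
  onef <- point_mass_posterior(qlogis(0.25), log(1.5), 0.8, g)
  expect_equal(cchange_ratio(dd, base, onef, 0.25), 1 / 3)
  # huge shift flips everyone -> 1
  allf <- point_mass_posterior(qlogis(0.25) + 5, log(1.5), 2, g)
  dd2 <- trial_data(c(1, 2, 3), c(0, 0, 0), matrix(c(1, 2, 3), 3, 1))
  expect_equal(cchange_ratio(dd2, base, allf, 0.25), 1)
  expect_error(cchange_ratio(trial_data(), base, same, 0.25), "empty")
})

test_that("update_inclusion is strict, per-covariate, and irreversible", {
  st <- pmtddesign:::new_inclusion_state(2)
  st <- update_inclusion(st, ratios = c(0.4, 0.1), thresholds = c(0.2, 0.2))
  expect_identical(st$included, c(TRUE, FALSE))
  # already-included stays even at ratio 0; exact threshold does not include
  st <- update_inclusion(st, ratios = c(0, 0.2), thresholds = c(0.2, 0.2))
  expect_identical(st$included, c(TRUE, FALSE))
  st <- update_inclusion(st, ratios = c(NA, 0.21), thresholds = c(0.2, 0.2))
  expect_identical(st$included, c(TRUE, TRUE))
  expect_length(st$history, 3)
})

test_that("run_trial structure: cohorts, start dose, determinism", {
  g <- bench_grid()
  s3 <- scenario_truth("logistic", g, s3_coeffs())
  des <- design_spec("blrm")
  r1 <- run_trial(s3, des, seed = 77)
  expect_equal(r1$n_cohorts, 10)
  expect_equal(r1$data$n, 30)
  expect_true(all(r1$allocations[[1]] == 1))
  expect_true(all(r1$data$dose_index %in% 1:5))
  r2 <- run_trial(s3, des, seed = 77)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$allocations, r2$allocations)
})

test_that("a DLT-free dose-toxicity truth escalates to the top dose and stays", {
  g <- bench_grid()
  tr <- scenario_truth("logistic", g, c(-15, 1))  # p ~ 0 everywhere
  rec <- run_trial(tr, design_spec("blrm"), seed = 5)
  expect_true(all(rec$data$y == 0))
  late <- unlist(rec$allocations[5:10])
  expect_true(all(late == 5))
})

test_that("cchange with thresholds > 1 walks the exact BLRM path", {
  g <- bench_grid()
  cs <- covariate_spec("normal")
  tr <- calibrate_truth(c(0.003, 0.07, 0.24, 0.45, 0.62), "logistic", g,
                        fixed_gamma = 1.5, covariates = cs)
  des_c <- design_spec("cchange", covariate_kinds = "normal",
                       cchange_thresholds = 1.5, settings = desk_mcmc())
  des_b <- design_spec("blrm")
  rc <- run_trial(tr, des_c, seed = 31)
  rb <- run_trial(tr, des_b, seed = 31)
  expect_false(any(rc$inclusion$included))
  expect_identical(rc$allocations, rb$allocations)
  expect_identical(rc$data$y, rb$data$y)
  expect_identical(rc$data$X, rb$data$X)
})

test_that("cchange with threshold 0 includes at the first disagreement; inclusion is monotone", {
  g <- bench_grid()
  cs <- covariate_spec("normal")
  tr <- calibrate_truth(c(0.003, 0.07, 0.24, 0.45, 0.62), "logistic", g,
                        fixed_gamma = 1.5, covariates = cs)
  des <- design_spec("cchange", covariate_kinds = "normal",
                     cchange_thresholds = 0, settings = desk_mcmc())
  rec <- run_trial(tr, des, seed = 13)
  hist <- rec$inclusion$history
  first_disagree <- which(vapply(hist, function(r)
    any(!is.na(r) & r > 0), logical(1)))[1]
  if (!is.na(first_disagree)) {
    expect_true(rec$inclusion$included[1])
    # every later cohort reports NA (not re-evaluated) for the included one
    expect_true(all(vapply(hist[-seq_len(first_disagree)],
                           function(r) is.na(r[1]), logical(1))))
  }
  # monotone included-set over a regular-threshold trial
  des2 <- design_spec("cchange", covariate_kinds = "normal",
                      settings = desk_mcmc())
  rec2 <- run_trial(tr, des2, seed = 14)
  state <- pmtddesign:::new_inclusion_state(1)
  sizes <- integer(0)
  for (r in rec2$inclusion$history) {
    state <- update_inclusion(state, r, des2$cchange_thresholds)
    sizes <- c(sizes, sum(state$included))
  }
  expect_true(all(diff(sizes) >= 0))
  expect_identical(state$included, rec2$inclusion$included)
})

test_that("design_spec validates its invariants", {
  expect_error(design_spec("blrm", n_total = 31), "n_total")
  expect_error(design_spec("blrmc"), "candidate covariate")
  expect_error(design_spec("blrm", covariate_kinds = "normal"),
               "does not use covariates")
})
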