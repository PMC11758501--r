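test_that("log_likelihood matches brute-force Bernoulli summation", {
  g <- bench_grid()
  # one patient at p = 0.5 with a DLT
  d1 <- trial_data(3, 1)
  expect_equal(log_likelihood(list(alpha = 0, log_beta = 0), d1, g), log(0.5))
  # empty data -> empty product
  expect_identical(log_likelihood(list(alpha = 1, log_beta = 1),
                                  trial_data(), g), 0)
  # 10 random patients, term-by-term oracle via dbinom
  dd <- tiny_data(10, seed = 4, p = 2)
  pars <- list(alpha = -0.6, log_beta = 0.3, gamma = c(0.5, -1))
  p_i <- plogis(-0.6 + exp(0.3) * log(g$doses[dd$dose_index] / 5) +
                  as.numeric(dd$X %*% pars$gamma))
  expect_equal(log_likelihood(pars, dd, g),
               sum(dbinom(dd$y, 1, p_i, log = TRUE)))
  expect_error(log_likelihood(list(alpha = 0, log_beta = 0, gamma = 1),
                              trial_data(1, 0), g), "covariate dimension")
})

test_that("log_prior evaluates each variant against direct formulas", {
  base <- list(alpha = -1, log_beta = 0.5)
  # p = 0 reduces to the bivariate normal alone (diagonal case oracle)
  sp0 <- prior_spec()
  expect_equal(log_prior(base, sp0),
               dnorm(-1, qlogis(0.1), 2, log = TRUE) +
                 dnorm(0.5, 0, 2, log = TRUE))
  # flat normal adds independent N(0, sigma2) terms
  spn <- prior_spec(c("normal", "binary"), type = "normal")
  expect_equal(log_prior(c(base, list(gamma = c(0.3, -0.2))), spn),
               log_prior(base, sp0) +
                 sum(dnorm(c(0.3, -0.2), 0, 2, log = TRUE)))
  # lasso at gamma = 0: Laplace term is log(lambda/2); hyperprior InvGamma
  spl <- prior_spec(c("normal", "normal"), type = "lasso")
  lam <- 0.7; del <- 0.4
  inv_gamma_ld <- del * log(del) - lgamma(del) - (del + 1) * log(lam) -
    del / lam
  expect_equal(log_prior(c(base, list(gamma = c(0, 0))), spl,
                         auxiliaries = list(lambda = lam)),
               log_prior(base, sp0) + 2 * log(lam / 2) + inv_gamma_ld)
  expect_identical(log_prior(c(base, list(gamma = c(0, 0))), spl,
                             auxiliaries = list(lambda = -1)), -Inf)
  # spike-and-slab vs direct mixture arithmetic at several gamma values
  sps <- prior_spec("normal", type = "spikeslab")
  for (gv in c(-1.4, 0, 0.2, 2.5)) {
    m <- 0.35
    direct <- log((1 - m) * dnorm(gv, 0, sqrt(0.05)) +
                    m * dnorm(gv, 0, sqrt(4))) +
      dbeta(m, 2, 2, log = TRUE)
    expect_equal(log_prior(c(base, list(gamma = gv)), sps,
                           auxiliaries = list(m = m)),
                 log_prior(base, sp0) + direct)
  }
  expect_identical(log_prior(c(base, list(gamma = 0)), sps,
                             auxiliaries = list(m = 1.2)), -Inf)
})

test_that("with no data the prior median toxicity at the reference dose is 0.1", {
  g <- bench_grid()
  f <- fit_posterior(prior_spec(), trial_data(), g)
  expect_equal(pmtddesign:::posterior_prob_quantile(f, 3, 0.5), 0.1,
               tolerance = 0.005)
})

test_that("cross-engine agreement: quadrature vs MCMC within 0.01", {
  g <- bench_grid()
  dd <- tiny_data(12, seed = 21)
  fq <- fit_posterior(prior_spec(), dd, g)
  fm <- fit_posterior(prior_spec(), dd, g, engine = "mcmc",
                      settings = list(chains = 4, warmup = 1000,
                                      iter = 2000), seed = 8)
  expect_lt(max(abs(fq$phat - estimate_prob(fm, 1:5))), 0.01)
  # randomized suite of 2-parameter fits
  set.seed(31)
  for (i in 1:5) {
    d2 <- tiny_data(9 + 3 * i, seed = 100 + i)
    fq2 <- fit_posterior(prior_spec(), d2, g)
    fm2 <- fit_posterior(prior_spec(), d2, g, engine = "mcmc",
                         settings = list(chains = 4, warmup = 1000,
                                         iter = 5000), seed = 200 + i)
    expect_lt(max(abs(fq2$phat - estimate_prob(fm2, 1:5))), 0.01)
  }
})

test_that("one-covariate grid quadrature agrees with MCMC", {
  g <- bench_grid()
  dd <- tiny_data(15, seed = 6, p = 1)
  pr <- prior_spec("normal", type = "normal")
  fq <- fit_posterior(pr, dd, g, engine = "quadrature")
  fm <- fit_posterior(pr, dd, g, engine = "mcmc",
                      settings = list(chains = 4, warmup = 1000,
                                      iter = 2000), seed = 77)
  for (x in c(-1, 0, 1.5))
    expect_lt(max(abs(estimate_prob(fq, 1:5, x) -
                        estimate_prob(fm, 1:5, x))), 0.015)
})

test_that("degenerate spike-and-slab collapses to the covariate-free fit", {
  g <- bench_grid()
  dd <- tiny_data(12, seed = 13, p = 1)
  # spike variance -> 0 and the weight pinned to the spike force gamma ~ 0
  pr <- prior_spec("normal", type = "spikeslab",
                   spike_var = c(normal = 1e-8, binary = 1e-8),
                   b1 = 0.05, b2 = 50)
  fs <- fit_posterior(pr, dd, g, engine = "mcmc",
                      settings = list(chains = 4, warmup = 1000,
                                      iter = 5000), seed = 5)
  f0 <- fit_posterior(prior_spec(), dd, g)
  expect_lt(max(abs(estimate_prob(fs, 1:5, 0) - f0$phat)), 0.02)
})

test_that("near-equal spike and slab variances reproduce the flat-normal fit", {
  g <- bench_grid()
  dd <- tiny_data(12, seed = 14, p = 1)
  pr_ss <- prior_spec("normal", type = "spikeslab",
                      spike_var = c(normal = 3.999, binary = 3.999))
  pr_n <- prior_spec("normal", type = "normal")
  fs <- fit_posterior(pr_ss, dd, g, engine = "mcmc",
                      settings = list(chains = 4, warmup = 1000,
                                      iter = 2000), seed = 9)
  fn <- fit_posterior(pr_n, dd, g, engine = "mcmc",
                      settings = list(chains = 4, warmup = 1000,
                                      iter = 2000), seed = 10)
  for (x in c(-1, 0, 1))
    expect_lt(max(abs(estimate_prob(fs, 1:5, x) -
                        estimate_prob(fn, 1:5, x))), 0.02)
})

test_that("estimate_prob contracts: dimensions, draw-average oracle, ordering", {
  g <- bench_grid()
  dd <- tiny_data(12, seed = 3)
  f0 <- fit_posterior(prior_spec(), dd, g)
  expect_error(estimate_prob(f0, 2, covariates = 1), "0 covariate")
  dd1 <- tiny_data(12, seed = 3, p = 1)
  fm <- fit_posterior(prior_spec("normal", type = "normal"), dd1, g,
                      engine = "mcmc", settings = desk_mcmc(), seed = 44)
  # recompute the posterior-mean curve externally from exported draws
  path <- tempfile(fileext = ".csv")
  write_posterior_draws(fm, path)
  D <- read.csv(path)
  x <- 0.8
  manual <- sapply(1:5, function(k)
    mean(plogis(D$alpha + exp(D$log_beta) * log(g$doses[k] / 5) +
                  D$gamma_1 * x)))
  expect_equal(unname(estimate_prob(fm, 1:5, x)), manual, tolerance = 1e-12)
  # patient-order invariance (likelihood is exchangeable; same seed)
  perm <- sample(seq_len(dd1$n))
  ddp <- trial_data(dd1$dose_index[perm], dd1$y[perm],
                    dd1$X[perm, , drop = FALSE])
  fmp <- fit_posterior(prior_spec("normal", type = "normal"), ddp, g,
                       engine = "mcmc", settings = desk_mcmc(), seed = 44)
  expect_identical(fm$draws, fmp$draws)
})

test_that("an added DLT at a dose never lowers its estimated toxicity", {
  g <- bench_grid()
  set.seed(17)
  for (i in 1:10) {
    dd <- tiny_data(9 + i, seed = 300 + i)
    f_before <- fit_posterior(prior_spec(), dd, g)
    k <- sample(1:5, 1)
    dd2 <- trial_data(c(dd$dose_index, k), c(dd$y, 1))
    f_after <- fit_posterior(prior_spec(), dd2, g)
    expect_gte(f_after$phat[k], f_before$phat[k] - 0.005)
  }
})

test_that("MCMC is reproducible under a fixed seed and reports diagnostics", {
  g <- bench_grid()
  dd <- tiny_data(12, seed = 2)
  f1 <- fit_posterior(prior_spec(), dd, g, engine = "mcmc",
                      settings = desk_mcmc(), seed = 123)
  f2 <- fit_posterior(prior_spec(), dd, g, engine = "mcmc",
                      settings = desk_mcmc(), seed = 123)
  expect_identical(f1$draws, f2$draws)
  expect_true(all(is.finite(f1$diagnostics$rhat)))
  expect_lt(f1$diagnostics$max_rhat, 1.1)
})
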