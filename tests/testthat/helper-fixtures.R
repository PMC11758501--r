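# Shared fixtures, built in code.

bench_grid <- function() dose_grid(c(1, 3, 5, 7, 9), 5)

# scenario-3 logistic coefficients recovered from its (d3, d4) anchor cells
s3_coeffs <- function() {
  a <- qlogis(0.24)
  b <- (qlogis(0.45) - a) / log(7 / 5)
  c(a, b)
}

# small deterministic patient history: doses spread over the grid
tiny_data <- function(n = 12, seed = 99, p = 0) {
  set.seed(seed)
  doses <- rep(1:4, length.out = n)
  X <- if (p > 0) matrix(rnorm(n * p), n, p) else matrix(0, n, 0)
  eta <- -1 + 0.8 * log(c(1, 3, 5, 7, 9)[doses] / 5) +
    (if (p > 0) rowSums(X) * 0.5 else 0)
  trial_data(doses, rbinom(n, 1, plogis(eta)), X)
}

# point-mass "posterior" whose probability curve is fully controlled;
# engine-compatible with estimate_prob_matrix (quadrature layout).
# gamma = NULL builds a covariate-free (p = 0) estimate.
point_mass_posterior <- function(alpha, log_beta, gamma = NULL, grid) {
  phat <- plogis(alpha + exp(log_beta) * log(grid$doses /
                                               grid$reference_dose))
  structure(list(engine = "quadrature", grid = grid,
                 p = if (is.null(gamma)) 0L else 1L,
                 TH = matrix(c(alpha, log_beta, gamma), 1),
                 weights = 1, phat = phat, diagnostics = list()),
            class = "posterior_estimate")
}

desk_mcmc <- function() list(chains = 2, warmup = 500, iter = 500)
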