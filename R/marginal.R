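# Gauss-Hermite quadrature for the standard normal weight (probabilists'
# convention): nodes/weights of the Jacobi matrix via Golub-Welsch.  Weights
# sum to 1, so E[f(Z)] ~ sum(w * f(z)) for Z ~ N(0,1).
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(nodes = 0, weights = 1))
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1))
  J[cbind(1:(n - 1), 2:n)] <- off
  J[cbind(2:n, 1:(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = (e$vectors[1, ]^2)[ord])
}

#' Draw covariate matrices from a covariate specification
#'
#' Continuous covariates are drawn jointly normal with the specification's
#' correlation (unit-variance marginals scaled by `sds`); binary covariates
#' are independent Bernoulli.
#'
#' @param spec A [covariate_spec()].
#' @param n Number of rows (patients).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used (so the call composes into a larger seeded simulation).
#' @return An `n` by `p` numeric matrix (0 columns when the specification is
#'   empty).
#' @export
gen_covariates <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "covariate_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- n_covariates(spec)
  X <- matrix(0, n, p)
  is_bin <- spec$kinds == "binary"
  nc <- sum(!is_bin)
  if (nc > 0) {
    Z <- matrix(rnorm(n * nc), n, nc)
    L <- chol(spec$correlation)
    Z <- Z %*% L
    cont_idx <- which(!is_bin)
    X[, cont_idx] <- sweep(sweep(Z, 2, spec$sds[cont_idx], `*`),
                           2, spec$means[cont_idx], `+`)
  }
  for (j in which(is_bin)) X[, j] <- rbinom(n, 1, spec$probs[j])
  colnames(X) <- if (p > 0) paste0("x", seq_len(p)) else NULL
  X
}

# Deterministic integration support for a covariate spec: a matrix of
# covariate points and a weight vector summing to 1.  Continuous covariates
# use tensor Gauss-Hermite (rotated by the Cholesky factor of the
# correlation); binary covariates are enumerated exactly.
covariate_quadrature <- function(spec, nodes = 40) {
  p <- n_covariates(spec)
  if (p == 0) return(list(points = matrix(0, 1, 0), weights = 1))
  is_bin <- spec$kinds == "binary"
  nc <- sum(!is_bin)
  if (nc > 2)
    stop("quadrature marginalization supports at most 2 continuous ",
         "covariates; use method = 'mc'")
  gh <- gauss_hermite(nodes)
  if (nc == 0) {
    pts_c <- matrix(0, 1, 0); w_c <- 1
  } else if (nc == 1) {
    pts_c <- matrix(gh$nodes, ncol = 1); w_c <- gh$weights
  } else {
    gm <- as.matrix(expand.grid(gh$nodes, gh$nodes))
    L <- chol(spec$correlation)
    pts_c <- gm %*% L
    w_c <- as.numeric(outer(gh$weights, gh$weights))
  }
  cont_idx <- which(!is_bin)
  if (nc > 0)
    pts_c <- sweep(sweep(pts_c, 2, spec$sds[cont_idx], `*`),
                   2, spec$means[cont_idx], `+`)
  # enumerate binary block
  bin_idx <- which(is_bin)
  if (length(bin_idx) > 0) {
    combos <- as.matrix(expand.grid(rep(list(c(0, 1)), length(bin_idx))))
    w_b <- apply(combos, 1, function(z)
      prod(ifelse(z == 1, spec$probs[bin_idx], 1 - spec$probs[bin_idx])))
  } else {
    combos <- matrix(0, 1, 0); w_b <- 1
  }
  n_c <- nrow(pts_c); n_b <- nrow(combos)
  points <- matrix(0, n_c * n_b, p)
  points[, cont_idx] <- pts_c[rep(seq_len(n_c), times = n_b), , drop = FALSE]
  points[, bin_idx] <- combos[rep(seq_len(n_b), each = n_c), , drop = FALSE]
  list(points = points,
       weights = as.numeric(w_c[rep(seq_len(n_c), times = n_b)] *
                            w_b[rep(seq_len(n_b), each = n_c)]))
}

#' Marginal (average) toxicity probability of a dose
#'
#' Integrates the true conditional toxicity probability over the covariate
#' distribution, \eqn{p_T(d) = \int p_T(d \mid x)\, q(x)\, dx}.  This is the
#' quantity scenario calibration matches to target tables, and it defines the
#' "average MTD" of a covariate scenario.
#'
#' @param truth A [scenario_truth()].
#' @param dose_index Integer dose level(s).
#' @param control List of integration settings: `method` (`"quadrature"`,
#'   the default for up to two continuous covariates, or `"mc"`), `nodes`
#'   (Gauss-Hermite nodes per continuous dimension, default 40), `n_mc`
#'   (Monte Carlo draws, default 1e5) and `seed` (for `"mc"`).
#' @return Numeric vector of marginal probabilities over `dose_index`.
#' @export
marginal_prob <- function(truth, dose_index = seq_len(n_doses(truth$grid)),
                          control = list()) {
  ctl <- modifyList(list(method = "quadrature", nodes = 40, n_mc = 1e5,
                         seed = NULL), control)
  check_dose_index(truth$grid, dose_index)
  if (length(truth$gamma) == 0 || all(truth$gamma == 0))
    return(true_prob(truth, dose_index, rep(0, length(truth$gamma))))
  if (ctl$method == "mc") {
    X <- gen_covariates(truth$covariates, ctl$n_mc, seed = ctl$seed)
    w <- rep(1 / nrow(X), nrow(X))
  } else {
    q <- covariate_quadrature(truth$covariates, nodes = ctl$nodes)
    X <- q$points; w <- q$weights
  }
  shift <- as.numeric(X %*% truth$gamma)
  vapply(dose_index, function(k) {
    base <- logit(true_prob(truth, k, rep(0, length(truth$gamma))))
    sum(w * invlogit(base + shift))
  }, numeric(1))
}

#' Population distribution of the personalized MTD
#'
#' Monte Carlo estimate of \eqn{P(\mathrm{pMTD} = d_k)} when covariates are
#' drawn from the scenario's covariate distribution.
#'
#' @param truth A [scenario_truth()].
#' @param n_draws Number of simulated patients.
#' @param seed Optional integer seed.
#' @return Named probability vector over doses (sums to 1).
#' @export
pmtd_distribution <- function(truth, n_draws = 1e4, seed = NULL) {
  stopifnot(n_draws >= 1)
  K <- n_doses(truth$grid)
  if (length(truth$gamma) == 0 || all(truth$gamma == 0)) {
    out <- numeric(K)
    out[true_pmtd(truth, rep(0, length(truth$gamma)))] <- 1
  } else {
    X <- gen_covariates(truth$covariates, n_draws, seed = seed)
    idx <- pmtd_of_rows(truth, X)
    out <- tabulate(idx, nbins = K) / n_draws
  }
  names(out) <- paste0("d", seq_len(K))
  out
}

# vectorized true pMTD over the rows of a covariate matrix
pmtd_of_rows <- function(truth, X) {
  K <- n_doses(truth$grid)
  base <- logit(vapply(seq_len(K), function(k)
    true_prob(truth, k, rep(0, length(truth$gamma))), numeric(1)))
  shift <- if (length(truth$gamma)) as.numeric(X %*% truth$gamma) else
    rep(0, nrow(X))
  P <- invlogit(outer(shift, base, `+`))   # n x K
  select_dose_rows(P, truth$tau)
}
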