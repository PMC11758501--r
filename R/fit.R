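# ---- quadrature engine ----------------------------------------------------

# Dense-grid quadrature for the 2-parameter model: precomputes, for a prior
# and dose grid, the (alpha, log beta) nodes, their log prior, and the
# per-dose toxicity probabilities at every node.  Repeated fits then reduce
# to per-dose sufficient statistics, which is what makes large BLRM
# operating-characteristics runs cheap.
quad_engine <- function(prior, grid, nodes = 201, span = 6) {
  s1 <- sqrt(prior$cov[1, 1]); s2 <- sqrt(prior$cov[2, 2])
  a <- seq(prior$mean[1] - span * s1, prior$mean[1] + span * s1,
           length.out = nodes)
  b <- seq(prior$mean[2] - span * s2, prior$mean[2] + span * s2,
           length.out = nodes)
  TH <- cbind(alpha = rep(a, times = nodes), log_beta = rep(b, each = nodes))
  prec <- solve(prior$cov)
  z1 <- TH[, 1] - prior$mean[1]; z2 <- TH[, 2] - prior$mean[2]
  logprior <- -0.5 * (prec[1, 1] * z1^2 + 2 * prec[1, 2] * z1 * z2 +
                        prec[2, 2] * z2^2)
  lr <- log_dose_ratio(grid)
  P <- vapply(lr, function(l) clamp_prob(invlogit(TH[, 1] +
                                                    exp(TH[, 2]) * l)),
              numeric(nrow(TH)))
  list(TH = TH, logprior = logprior, P = P, logP = log(P),
       log1mP = log1p(-P), grid = grid, prior = prior,
       nodes = nodes, span = span)
}

# posterior from per-dose counts (y_k DLTs out of n_k) on a cached engine
quad_fit_counts <- function(eng, y_k, n_k) {
  lp <- eng$logprior + as.numeric(eng$logP %*% y_k +
                                    eng$log1mP %*% (n_k - y_k))
  w <- exp(lp - max(lp)); w <- w / sum(w)
  structure(list(engine = "quadrature", prior = eng$prior, grid = eng$grid,
                 p = 0L, TH = eng$TH, weights = w,
                 phat = as.numeric(crossprod(eng$P, w)),
                 P = eng$P, diagnostics = list(nodes = eng$nodes)),
            class = "posterior_estimate")
}

dose_counts <- function(data, grid) {
  K <- n_doses(grid)
  n_k <- tabulate(data$dose_index, nbins = K)
  y_k <- vapply(seq_len(K), function(k) sum(data$y[data$dose_index == k]),
                numeric(1))
  list(y_k = y_k, n_k = n_k)
}

# 3-D grid quadrature for one flat-normal covariate coefficient
quad_fit_p1 <- function(prior, data, grid, nodes = 61, span = 6) {
  if (prior$type != "normal")
    stop("grid quadrature with a covariate supports the flat-normal ",
         "covariate prior only; use engine = 'mcmc'")
  s1 <- sqrt(prior$cov[1, 1]); s2 <- sqrt(prior$cov[2, 2])
  sg <- sqrt(prior$sigma2[1])
  a <- seq(prior$mean[1] - span * s1, prior$mean[1] + span * s1,
           length.out = nodes)
  b <- seq(prior$mean[2] - span * s2, prior$mean[2] + span * s2,
           length.out = nodes)
  g <- seq(-span * sg, span * sg, length.out = nodes)
  TH <- as.matrix(expand.grid(alpha = a, log_beta = b, gamma_1 = g))
  prec <- solve(prior$cov)
  z1 <- TH[, 1] - prior$mean[1]; z2 <- TH[, 2] - prior$mean[2]
  lp <- -0.5 * (prec[1, 1] * z1^2 + 2 * prec[1, 2] * z1 * z2 +
                  prec[2, 2] * z2^2) - 0.5 * TH[, 3]^2 / prior$sigma2[1]
  if (data$n > 0) {
    lr <- log_dose_ratio(grid)
    beta <- exp(TH[, 2])
    for (i in seq_len(data$n)) {
      eta <- TH[, 1] + beta * lr[data$dose_index[i]] +
        TH[, 3] * data$X[i, 1]
      pi <- clamp_prob(invlogit(eta))
      lp <- lp + if (data$y[i] == 1) log(pi) else log1p(-pi)
    }
  }
  w <- exp(lp - max(lp)); w <- w / sum(w)
  structure(list(engine = "quadrature", prior = prior, grid = grid, p = 1L,
                 TH = TH, weights = w, diagnostics = list(nodes = nodes)),
            class = "posterior_estimate")
}

# ---- MCMC engine ----------------------------------------------------------

mcmc_defaults <- function() list(chains = 4, warmup = 1000, iter = 1000,
                                 init_step = 0.5, rhat_warn = 1.1)

prior_to_cpp <- function(prior) {
  out <- list(type = switch(prior$type, none = 0L, normal = 1L, lasso = 2L,
                            spikeslab = 3L),
              mean = prior$mean, prec = solve(prior$cov))
  if (prior$type == "normal") out$sigma2 <- prior$sigma2
  if (prior$type == "lasso") {
    out$group <- as.integer(prior$group - 1L)
    out$group_delta <- prior$group_delta
  }
  if (prior$type == "spikeslab") {
    out$b1 <- prior$b1; out$b2 <- prior$b2
    out$slab_var <- prior$slab_var; out$spike_var <- prior$spike_var
    out$swap <- prior$swap_components
  }
  out
}

param_names <- function(prior) {
  p <- n_model_covariates(prior)
  nm <- c("alpha", "log_beta", if (p) paste0("gamma_", seq_len(p)))
  if (prior$type == "lasso")
    nm <- c(nm, paste0("log_lambda_", seq_along(prior$group_delta)))
  if (prior$type == "spikeslab")
    nm <- c(nm, paste0("logit_m_", seq_len(p)))
  nm
}

mcmc_fit <- function(prior, data, grid, settings, seed) {
  st <- modifyList(mcmc_defaults(), settings)
  p <- n_model_covariates(prior)
  if (!is.null(seed)) set.seed(seed)
  nm <- param_names(prior)
  dim <- length(nm)
  init <- matrix(rep(c(prior$mean, rep(0, dim - 2)), each = st$chains),
                 st$chains, dim)
  init <- init + matrix(rnorm(st$chains * dim, 0, 0.5), st$chains, dim)
  X <- if (p > 0) data$X[, seq_len(p), drop = FALSE] else
    matrix(0, data$n, 0)
  res <- blrm_mcmc_cpp(as.integer(data$y),
                       log_dose_ratio(grid)[data$dose_index],
                       X, prior_to_cpp(prior),
                       st$chains, st$warmup, st$iter, init, st$init_step)
  draws <- res$draws
  colnames(draws) <- nm
  rhat <- apply_split_rhat(draws, res$chain)
  diag <- list(engine = "mcmc", chains = st$chains, warmup = st$warmup,
               iter = st$iter, accept_rate = res$accept_rate, rhat = rhat,
               max_rhat = max(rhat), seed = seed,
               converged = max(rhat) < st$rhat_warn)
  structure(list(engine = "mcmc", prior = prior, grid = grid, p = p,
                 draws = draws, chain = res$chain, diagnostics = diag),
            class = "posterior_estimate")
}

# split-Rhat (each chain halved) per parameter column
apply_split_rhat <- function(draws, chain) {
  grp <- character(nrow(draws))
  for (cc in unique(chain)) {
    idx <- which(chain == cc)
    h <- rep(1:2, each = ceiling(length(idx) / 2))[seq_along(idx)]
    grp[idx] <- paste0(cc, ".", h)
  }
  apply(draws, 2, function(x) {
    xs <- split(x, grp)
    m <- lengths(xs)[1]
    W <- mean(vapply(xs, var, numeric(1)))
    B <- m * var(vapply(xs, mean, numeric(1)))
    if (W <= 0) return(1)
    sqrt(((m - 1) / m * W + B / m) / W)
  })
}

# ---- public fitting interface ---------------------------------------------

#' Fit the posterior of a dose-toxicity model
#'
#' Computes the posterior of \eqn{(\alpha, \log\beta, \gamma)} given trial
#' data under a [prior_spec()], using either dense grid quadrature (exact up
#' to grid resolution; available for the covariate-free model and for one
#' flat-normal covariate) or adaptive random-walk Metropolis MCMC (any
#' model).  The returned object estimates the posterior *mean* of
#' \eqn{p_T(d \mid x)} — not the plug-in probability at posterior-mean
#' parameters — via [estimate_prob()].
#'
#' @param prior A [prior_spec()].
#' @param data A [trial_data()] whose covariate columns match (or exceed —
#'   extra columns are ignored) the prior's covariate count.
#' @param grid A [dose_grid()].
#' @param engine `"auto"` (quadrature when available, else MCMC),
#'   `"quadrature"` or `"mcmc"`.
#' @param settings Engine knobs.  Quadrature: `nodes` (per-dimension grid
#'   resolution, default 201 for 2 parameters, 61 for 3), `span` (half-width
#'   in prior SDs, default 6).  MCMC: `chains` (4), `warmup` (1000), `iter`
#'   (kept draws per chain, 1000), `init_step` (0.5).
#' @param seed Optional integer seed (MCMC only); with a fixed seed repeat
#'   calls are identical.
#' @return A `posterior_estimate` object with a `diagnostics` element
#'   (split-Rhat and acceptance rate for MCMC).
#' @export
fit_posterior <- function(prior, data, grid,
                          engine = c("auto", "quadrature", "mcmc"),
                          settings = list(), seed = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(prior, "prior_spec"), inherits(data, "trial_data"),
            inherits(grid, "dose_grid"))
  p <- n_model_covariates(prior)
  if (data$n > 0 && ncol(data$X) < p)
    stop("data has fewer covariate columns than the prior expects")
  if (engine == "auto") engine <- if (p == 0) "quadrature" else "mcmc"
  if (engine == "quadrature") {
    if (p == 0) {
      nodes <- settings$nodes %||% 201
      span <- settings$span %||% 6
      eng <- settings$engine_cache %||% quad_engine(prior, grid, nodes, span)
      cnt <- dose_counts(data, grid)
      return(quad_fit_counts(eng, cnt$y_k, cnt$n_k))
    }
    if (p > 1) stop("quadrature supports at most one covariate; use MCMC")
    return(quad_fit_p1(prior, data, grid,
                       nodes = settings$nodes %||% 61,
                       span = settings$span %||% 6))
  }
  mcmc_fit(prior, data, grid, settings, seed)
}

#' @export
print.posterior_estimate <- function(x, ...) {
  cat("<posterior_estimate>", x$engine, "fit,", x$p, "covariate(s)\n")
  if (x$engine == "mcmc")
    cat("  chains:", x$diagnostics$chains, " max split-Rhat:",
        round(x$diagnostics$max_rhat, 3), "\n")
  invisible(x)
}

#' Posterior-mean DLT probability
#'
#' @param post A `posterior_estimate` from [fit_posterior()].
#' @param dose_index Integer dose level(s).
#' @param covariates Covariate vector of length equal to the fitted model's
#'   covariate count.  Supplying covariates to a covariate-free (BLRM) fit
#'   is an error.
#' @return Posterior mean of \eqn{p_T(d_k \mid x)} for each requested dose.
#' @export
estimate_prob <- function(post, dose_index, covariates = numeric()) {
  stopifnot(inherits(post, "posterior_estimate"))
  check_dose_index(post$grid, dose_index)
  if (length(covariates) != post$p)
    stop("model was fitted with ", post$p, " covariate(s); got ",
         length(covariates))
  if (post$p == 0 && post$engine == "quadrature")
    return(post$phat[dose_index])
  drop(estimate_prob_matrix(post, matrix(covariates, nrow = 1))[1,
       dose_index])
}

#' Posterior-mean DLT probabilities for a set of patients
#'
#' @param post A `posterior_estimate`.
#' @param X Covariate matrix, one row per patient (its first `post$p`
#'   columns are used; pass a 0-column matrix for a BLRM fit).
#' @return Matrix of posterior-mean probabilities, patients by doses.
#' @export
estimate_prob_matrix <- function(post, X) {
  stopifnot(inherits(post, "posterior_estimate"))
  X <- as.matrix(X)
  n <- nrow(X)
  K <- n_doses(post$grid)
  lr <- log_dose_ratio(post$grid)
  if (post$p == 0) {
    phat <- if (post$engine == "quadrature") post$phat else
      vapply(seq_len(K), function(k)
        mean(invlogit(post$draws[, 1] + exp(post$draws[, 2]) * lr[k])),
        numeric(1))
    return(matrix(phat, n, K, byrow = TRUE))
  }
  if (ncol(X) < post$p) stop("covariate matrix has too few columns")
  Xm <- X[, seq_len(post$p), drop = FALSE]
  if (post$engine == "quadrature") {
    TH <- post$TH; w <- post$weights
    shift <- TH[, 3, drop = FALSE] %*% t(Xm)   # nodes x n (p = 1 only)
    out <- vapply(seq_len(K), function(k) {
      eta <- TH[, 1] + exp(TH[, 2]) * lr[k]
      as.numeric(crossprod(invlogit(eta + shift), w))
    }, numeric(n))
  } else {
    D <- post$draws
    gam <- D[, 2 + seq_len(post$p), drop = FALSE]
    shift <- gam %*% t(Xm)                     # draws x n
    beta <- exp(D[, 2])
    out <- vapply(seq_len(K), function(k)
      colMeans(invlogit(D[, 1] + beta * lr[k] + shift)), numeric(n))
  }
  matrix(out, n, K)
}

# weighted/empirical posterior quantile of p_T(d_k) at covariates x
posterior_prob_quantile <- function(post, dose_index, prob = 0.5,
                                    covariates = numeric()) {
  lr <- log_dose_ratio(post$grid)[dose_index]
  if (post$engine == "quadrature") {
    TH <- post$TH; w <- post$weights
    shift <- if (post$p > 0) as.numeric(TH[, 3] * covariates[1]) else 0
    vals <- invlogit(TH[, 1] + exp(TH[, 2]) * lr + shift)
    ord <- order(vals)
    cw <- cumsum(w[ord])
    vals[ord][which(cw >= prob)[1]]
  } else {
    D <- post$draws
    shift <- if (post$p > 0)
      as.numeric(D[, 2 + seq_len(post$p), drop = FALSE] %*% covariates)
    else 0
    unname(quantile(invlogit(D[, 1] + exp(D[, 2]) * lr + shift), prob))
  }
}

#' Export posterior draws as CSV
#'
#' Writes MCMC draws (columns `alpha`, `log_beta`, `gamma_*`, hyperparameter
#' columns, `chain`) for external auditing.
#'
#' @param post An MCMC `posterior_estimate`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_posterior_draws <- function(post, path) {
  if (post$engine != "mcmc") stop("draw export requires an MCMC fit")
  df <- as.data.frame(post$draws)
  df$chain <- post$chain
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
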