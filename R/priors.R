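#' Prior specification for the dose-toxicity model
#'
#' All designs share a bivariate normal prior on the intercept and log-slope
#' \eqn{(\alpha, \log\beta)}; the variants differ only in the prior placed on
#' the covariate coefficients \eqn{\gamma_j}:
#'
#' * `"none"` — no covariates in the model (the plain BLRM);
#' * `"normal"` — independent flat normals \eqn{\gamma_j \sim N(0, \sigma^2)}
#'   (the unpenalized BLRMc);
#' * `"lasso"` — Bayesian LASSO: \eqn{\gamma_j \mid \lambda_g \sim
#'   \mathrm{Laplace}(0, \lambda_g)} with density
#'   \eqn{(\lambda/2)e^{-\lambda|\gamma|}} and one rate \eqn{\lambda_g} per
#'   covariate *group* (continuous vs binary), each with hyperprior
#'   \eqn{\lambda_g \sim \mathrm{InvGamma}(\delta_g, \delta_g)};
#' * `"spikeslab"` — per-covariate two-component normal mixture
#'   \eqn{\gamma_j \mid m_j \sim (1-m_j) f_1 + m_j f_0} with spike \eqn{f_1 =
#'   N(0, \nu_j)} (small variance) and slab \eqn{f_0 = N(0,
#'   \sigma^2_{slab})}, and \eqn{m_j \sim \mathrm{Beta}(b_1, b_2)}.
#'
#' The mixture weight convention follows the printed model: the weight
#' \eqn{(1-m_j)} multiplies the lower-variance spike component.  Set
#' `swap_components = TRUE` to put \eqn{(1-m_j)} on the slab instead.
#'
#' @param covariate_kinds Character vector (`"normal"`/`"binary"`), one per
#'   covariate entering the *model* (empty for the BLRM).  Determines LASSO
#'   group membership and kind-specific hyperparameter defaults.
#' @param type Covariate-prior variant, see above.
#' @param mean,cov Mean vector and 2x2 covariance of the bivariate normal on
#'   \eqn{(\alpha, \log\beta)}; defaults `(logit(0.1), 0)` and `diag(4, 4)`,
#'   the weakly-informative prior whose implied prior median toxicity at the
#'   reference dose is 0.1.
#' @param sigma2 Flat-normal variance for `type = "normal"`; default 4.
#' @param delta Named vector `c(normal = , binary = )` of InvGamma
#'   hyperparameters per group for `type = "lasso"`.  Defaults to the
#'   calibrated values: 0.4 for both groups when all covariates are
#'   continuous, and `(normal = 1, binary = 0.4)` for mixed covariates.
#' @param b1,b2 Beta hyperparameters of the mixture weight; default (2, 2).
#' @param slab_var Slab variance; default 4 (matching the BLRMc variance).
#' @param spike_var Named vector `c(normal = , binary = )` of spike
#'   variances.  Defaults to the calibrated values: 0.05 when all covariates
#'   are continuous, `(normal = 0.1, binary = 0.05)` for mixed covariates.
#' @param swap_components Logical; see above. Default `FALSE`.
#' @return An object of class `prior_spec`.
#' @examples
#' prior_spec()                                        # BLRM
#' prior_spec(c("normal", "normal"), type = "normal")  # BLRMc2
#' prior_spec(c("normal", "binary"), type = "lasso")
#' @export
prior_spec <- function(covariate_kinds = character(),
                       type = c("none", "normal", "lasso", "spikeslab"),
                       mean = c(logit(0.1), 0), cov = diag(c(4, 4)),
                       sigma2 = 4, delta = NULL, b1 = 2, b2 = 2,
                       slab_var = 4, spike_var = NULL,
                       swap_components = FALSE) {
  type <- match.arg(type)
  covariate_kinds <- as.character(covariate_kinds)
  stopifnot(all(covariate_kinds %in% c("normal", "binary")))
  p <- length(covariate_kinds)
  if (p == 0 && type != "none") type <- "none"
  if (p > 0 && type == "none")
    stop("covariates supplied but covariate prior type is 'none'")
  cov <- as.matrix(cov)
  stopifnot(length(mean) == 2, all(dim(cov) == 2))
  ev <- eigen((cov + t(cov)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("base covariance must be positive-definite")
  mixed <- length(unique(covariate_kinds)) == 2
  out <- list(type = type, kinds = covariate_kinds,
              mean = as.numeric(mean), cov = cov,
              swap_components = isTRUE(swap_components))
  if (type == "normal") {
    stopifnot(sigma2 > 0)
    out$sigma2 <- rep_len(sigma2, p)
  } else if (type == "lasso") {
    if (is.null(delta))
      delta <- if (mixed) c(normal = 1, binary = 0.4)
               else c(normal = 0.4, binary = 0.4)
    stopifnot(all(delta > 0))
    out$delta <- delta[covariate_kinds]          # per-covariate lookup
    out$group <- match(covariate_kinds, unique(covariate_kinds))
    out$group_kind <- unique(covariate_kinds)
    out$group_delta <- unname(delta[out$group_kind])
  } else if (type == "spikeslab") {
    if (is.null(spike_var))
      spike_var <- if (mixed) c(normal = 0.1, binary = 0.05)
                   else c(normal = 0.05, binary = 0.05)
    stopifnot(b1 > 0, b2 > 0, slab_var > 0, all(spike_var > 0))
    nu <- unname(spike_var[covariate_kinds])
    if (any(nu >= slab_var))
      stop("spike variance must be smaller than the slab variance")
    out$b1 <- b1; out$b2 <- b2; out$slab_var <- slab_var; out$spike_var <- nu
  }
  class(out) <- "prior_spec"
  out
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("<prior_spec> (alpha, log beta) ~ BVN(",
      paste(signif(x$mean, 4), collapse = ", "), "; var ",
      paste(signif(diag(x$cov), 4), collapse = ", "), ")\n", sep = "")
  if (x$type == "none") cat("  no covariates (BLRM)\n")
  else cat("  covariate prior:", x$type, "on", length(x$kinds),
           "coefficient(s)\n")
  invisible(x)
}

n_model_covariates <- function(spec) length(spec$kinds)

# number of auxiliary parameters the sampler carries beyond (alpha, log beta,
# gamma): lasso log-rates per group, spike-slab logit-weights per covariate
n_aux <- function(spec) switch(spec$type,
  none = 0L, normal = 0L,
  lasso = length(spec$group_delta),
  spikeslab = length(spec$kinds))

#' Log prior density of the model parameters
#'
#' Evaluates the joint log density of \eqn{(\alpha, \log\beta)} under the
#' bivariate normal plus the covariate-coefficient prior, including any
#' hyperparameters (LASSO rates \eqn{\lambda_g}, mixture weights
#' \eqn{m_j}) at the supplied values.  Out-of-support hyperparameters
#' (\eqn{\lambda \le 0}, \eqn{m \notin [0,1]}) return `-Inf`.
#'
#' @param params List with elements `alpha`, `log_beta` and `gamma` (numeric
#'   vector, possibly empty).
#' @param spec A [prior_spec()].
#' @param auxiliaries List with `lambda` (per-group, `type = "lasso"`) and/or
#'   `m` (per-covariate, `type = "spikeslab"`), required exactly when the
#'   variant uses them.
#' @return Log density (real; `-Inf` out of support).
#' @export
log_prior <- function(params, spec, auxiliaries = list()) {
  stopifnot(inherits(spec, "prior_spec"))
  gamma <- params$gamma %||% numeric()
  if (length(gamma) != n_model_covariates(spec))
    stop("gamma length does not match the prior specification")
  z <- c(params$alpha, params$log_beta) - spec$mean
  pr <- solve(spec$cov)
  lp <- -log(2 * pi) - 0.5 * determinant(spec$cov, logarithm = TRUE)$modulus -
    0.5 * drop(t(z) %*% pr %*% z)
  lp <- as.numeric(lp)
  if (spec$type == "normal") {
    lp <- lp + sum(dnorm(gamma, 0, sqrt(spec$sigma2), log = TRUE))
  } else if (spec$type == "lasso") {
    lam <- auxiliaries$lambda
    if (is.null(lam) || length(lam) != length(spec$group_delta))
      stop("lasso prior requires one lambda per covariate group")
    if (any(lam <= 0)) return(-Inf)
    lam_j <- lam[spec$group]
    lp <- lp + sum(log(lam_j / 2) - lam_j * abs(gamma))
    d <- spec$group_delta
    lp <- lp + sum(d * log(d) - lgamma(d) - (d + 1) * log(lam) - d / lam)
  } else if (spec$type == "spikeslab") {
    m <- auxiliaries$m
    if (is.null(m) || length(m) != length(spec$kinds))
      stop("spike-and-slab prior requires one mixture weight per covariate")
    if (any(m < 0 | m > 1)) return(-Inf)
    w_spike <- if (spec$swap_components) m else 1 - m
    dens <- w_spike * dnorm(gamma, 0, sqrt(spec$spike_var)) +
      (1 - w_spike) * dnorm(gamma, 0, sqrt(spec$slab_var))
    lp <- lp + sum(log(dens)) + sum(dbeta(m, spec$b1, spec$b2, log = TRUE))
  }
  lp
}
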