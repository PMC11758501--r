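#' Dose grid for a dose-finding trial
#'
#' An ordered set of dose amounts together with the reference dose used to
#' standardize the log-dose covariate of the two-parameter logistic model.
#'
#' @param doses Numeric vector of strictly increasing, positive dose amounts
#'   (mg).
#' @param reference_dose Positive reference dose \eqn{d_r} (mg).  It need not
#'   be a member of the grid.
#' @return An object of class `dose_grid`.
#' @examples
#' dose_grid(c(1, 3, 5, 7, 9), reference_dose = 5)
#' @export
dose_grid <- function(doses, reference_dose) {
  doses <- as.numeric(doses)
  stopifnot(length(doses) >= 1, all(is.finite(doses)), all(doses > 0))
  if (is.unsorted(doses, strictly = TRUE))
    stop("`doses` must be strictly increasing")
  stopifnot(length(reference_dose) == 1, is.finite(reference_dose),
            reference_dose > 0)
  structure(list(doses = doses, reference_dose = as.numeric(reference_dose)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("<dose_grid> doses (mg):", paste(x$doses, collapse = ", "),
      "| reference:", x$reference_dose, "mg\n")
  invisible(x)
}

#' Number of dose levels
#' @param grid A [dose_grid()].
#' @return Integer number of doses.
#' @export
n_doses <- function(grid) length(grid$doses)

# log(d_k / d_r) for every dose level
log_dose_ratio <- function(grid) log(grid$doses / grid$reference_dose)

#' Covariate distribution specification
#'
#' Describes the joint distribution \eqn{q(x)} of the patient covariates used
#' both to generate trial populations and to marginalize dose-toxicity
#' probabilities.  Continuous covariates are normal (standard normal by
#' default, matching the assumption that real covariates are centered and
#' standardized before the trial); binary covariates are Bernoulli.
#' Correlation, if any, applies to the continuous block only; binary
#' covariates are always independent.
#'
#' @param kinds Character vector, each `"normal"` or `"binary"`.
#' @param means Numeric vector of means for normal covariates (ignored for
#'   binary ones); default 0.
#' @param sds Numeric vector of standard deviations for normal covariates;
#'   default 1.
#' @param probs Numeric vector of success probabilities in (0,1) for binary
#'   covariates (ignored for normal ones); default 0.5.
#' @param correlation Correlation matrix over the continuous covariates
#'   (identity by default).  Must be symmetric positive-definite with unit
#'   diagonal.
#' @return An object of class `covariate_spec`.
#' @examples
#' covariate_spec(c("normal", "normal"))                   # two iid N(0,1)
#' covariate_spec(c("normal", "binary"), probs = c(NA, 0.5))
#' covariate_spec(c("normal", "normal"),
#'                correlation = matrix(c(1, .8, .8, 1), 2))
#' @export
covariate_spec <- function(kinds = character(), means = NULL, sds = NULL,
                           probs = NULL, correlation = NULL) {
  kinds <- as.character(kinds)
  stopifnot(all(kinds %in% c("normal", "binary")))
  p <- length(kinds)
  means <- rep_len(if (is.null(means)) 0 else as.numeric(means), p)
  sds <- rep_len(if (is.null(sds)) 1 else as.numeric(sds), p)
  probs <- rep_len(if (is.null(probs)) 0.5 else as.numeric(probs), p)
  is_bin <- kinds == "binary"
  if (any(is_bin)) {
    pb <- probs[is_bin]
    if (any(!is.finite(pb)) || any(pb <= 0) || any(pb >= 1))
      stop("Bernoulli probabilities must lie in (0,1)")
  }
  if (any(!is_bin) && any(sds[!is_bin] <= 0))
    stop("normal covariate standard deviations must be positive")
  n_cont <- sum(!is_bin)
  if (is.null(correlation)) correlation <- diag(n_cont) else {
    correlation <- as.matrix(correlation)
    if (!isTRUE(all.equal(dim(correlation), c(n_cont, n_cont))))
      stop("`correlation` must be ", n_cont, "x", n_cont,
           " (one row/col per continuous covariate)")
    if (max(abs(correlation - t(correlation))) > 1e-8 ||
        max(abs(diag(correlation) - 1)) > 1e-8)
      stop("`correlation` must be symmetric with unit diagonal")
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) stop("`correlation` must be positive-definite")
  }
  structure(list(kinds = kinds, means = means, sds = sds, probs = probs,
                 correlation = correlation),
            class = "covariate_spec")
}

#' @export
print.covariate_spec <- function(x, ...) {
  p <- length(x$kinds)
  if (p == 0) { cat("<covariate_spec> no covariates\n"); return(invisible(x)) }
  desc <- ifelse(x$kinds == "normal",
                 sprintf("N(%g, %g^2)", x$means, x$sds),
                 sprintf("Bern(%g)", x$probs))
  cat("<covariate_spec>", paste(desc, collapse = ", "), "\n")
  nc <- sum(x$kinds == "normal")
  if (nc > 1 && max(abs(x$correlation - diag(nc))) > 0) {
    cat("  continuous-block correlation:\n")
    print(x$correlation)
  }
  invisible(x)
}

#' Number of covariates in a specification
#' @param spec A [covariate_spec()].
#' @return Integer.
#' @export
n_covariates <- function(spec) length(spec$kinds)

#' True data-generating dose-toxicity model
#'
#' Bundles the dose-toxicity family (two-parameter logistic or Emax on the
#' logit scale), its coefficients, the covariate coefficients \eqn{\gamma},
#' the covariate distribution, and the target toxicity rate \eqn{\tau} into
#' the "truth" object that drives simulated trials.
#'
#' @param family `"logistic"` or `"emax"`.
#' @param grid A [dose_grid()].
#' @param coeffs For `family = "logistic"`, `c(alpha, beta)` of
#'   \eqn{\mathrm{logit}\,p = \alpha + \beta \log(d/d_r)}; for
#'   `family = "emax"`, `c(alpha1, alpha2, alpha3)` of
#'   \eqn{\mathrm{logit}\,p = \alpha_1 + \alpha_2 d/(d+\alpha_3)} with
#'   \eqn{\alpha_3 > 0}.
#' @param gamma Numeric vector of covariate coefficients (length equal to the
#'   number of covariates in `covariates`; may be empty).
#' @param covariates A [covariate_spec()]; defaults to no covariates.
#' @param tau Target toxicity rate in (0,1); default 0.25.
#' @return An object of class `scenario_truth`.
#' @examples
#' g <- dose_grid(c(1, 3, 5, 7, 9), 5)
#' scenario_truth("logistic", g, coeffs = c(-1.1527, 2.8294))
#' @export
scenario_truth <- function(family = c("logistic", "emax"), grid, coeffs,
                           gamma = numeric(), covariates = covariate_spec(),
                           tau = 0.25) {
  family <- match.arg(family)
  stopifnot(inherits(grid, "dose_grid"), inherits(covariates, "covariate_spec"))
  coeffs <- as.numeric(coeffs)
  if (family == "logistic" && length(coeffs) != 2)
    stop("logistic family needs coeffs = c(alpha, beta)")
  if (family == "emax") {
    if (length(coeffs) != 3) stop("emax family needs coeffs = c(a1, a2, a3)")
    if (coeffs[3] <= 0) stop("emax scale parameter alpha3 must be positive")
  }
  gamma <- as.numeric(gamma)
  if (length(gamma) != n_covariates(covariates))
    stop("length(gamma) must equal the number of covariates")
  stopifnot(length(tau) == 1, tau > 0, tau < 1)
  structure(list(family = family, grid = grid, coeffs = coeffs,
                 gamma = gamma, covariates = covariates, tau = tau),
            class = "scenario_truth")
}

#' @export
print.scenario_truth <- function(x, ...) {
  cat("<scenario_truth>", x$family, "family, tau =", x$tau, "\n")
  cat("  coeffs:", paste(signif(x$coeffs, 5), collapse = ", "))
  if (length(x$gamma))
    cat("  gamma:", paste(signif(x$gamma, 5), collapse = ", "))
  cat("\n")
  p <- sapply(seq_along(x$grid$doses), function(k)
    true_prob(x, k, rep(0, length(x$gamma))))
  cat("  p_T(d | x = 0):", paste(sprintf("%.3f", p), collapse = ", "), "\n")
  invisible(x)
}

#' Logistic dose-toxicity probability
#'
#' Evaluates \eqn{p_T(d_k \mid x) =
#' \mathrm{logit}^{-1}(\alpha + \beta\log(d_k/d_r) + \sum_j \gamma_j x_j)}.
#'
#' @param coeffs `c(alpha, beta)`.
#' @param grid A [dose_grid()].
#' @param dose_index Integer dose level (may be a vector).
#' @param covariates Numeric covariate vector \eqn{x} (possibly empty).
#' @param gamma Covariate coefficients, same length as `covariates`.
#' @return Probability (or vector of probabilities over `dose_index`).
#' @examples
#' g <- dose_grid(c(1, 3, 5, 7, 9), 5)
#' logistic_prob(c(-1.1527, 2.8294), g, 5)   # ~0.62
#' @export
logistic_prob <- function(coeffs, grid, dose_index, covariates = numeric(),
                          gamma = numeric()) {
  stopifnot(length(coeffs) == 2)
  check_dose_index(grid, dose_index)
  shift <- covariate_shift(covariates, gamma)
  invlogit(coeffs[1] + coeffs[2] * log_dose_ratio(grid)[dose_index] + shift)
}

#' Emax dose-toxicity probability (logit scale)
#'
#' Evaluates \eqn{p_T(d \mid x) =
#' \mathrm{logit}^{-1}(\alpha_1 + \alpha_2\, d/(d + \alpha_3)
#' + \sum_j \gamma_j x_j)}, the saturating dose-response form used for
#' model-misspecification sensitivity analyses.
#'
#' @param coeffs `c(alpha1, alpha2, alpha3)` with `alpha3 > 0`.
#' @inheritParams logistic_prob
#' @return Probability (or vector over `dose_index`).
#' @export
emax_prob <- function(coeffs, grid, dose_index, covariates = numeric(),
                      gamma = numeric()) {
  stopifnot(length(coeffs) == 3)
  if (coeffs[3] <= 0) stop("alpha3 must be positive")
  check_dose_index(grid, dose_index)
  d <- grid$doses[dose_index]
  shift <- covariate_shift(covariates, gamma)
  invlogit(coeffs[1] + coeffs[2] * d / (d + coeffs[3]) + shift)
}

covariate_shift <- function(covariates, gamma) {
  if (length(covariates) != length(gamma))
    stop("covariate vector and gamma must have the same length")
  if (length(gamma) == 0) 0 else sum(gamma * covariates)
}

check_dose_index <- function(grid, dose_index) {
  if (any(dose_index < 1) || any(dose_index > n_doses(grid)) ||
      any(dose_index != round(dose_index)))
    stop("invalid dose index")
  invisible(TRUE)
}

#' True conditional toxicity probability under a scenario
#'
#' @param truth A [scenario_truth()].
#' @param dose_index Integer dose level(s).
#' @param covariates Covariate vector conforming to `truth$covariates`.
#' @return Probability (or vector over `dose_index`).
#' @export
true_prob <- function(truth, dose_index, covariates = numeric()) {
  if (truth$family == "logistic")
    logistic_prob(truth$coeffs, truth$grid, dose_index, covariates,
                  truth$gamma)
  else
    emax_prob(truth$coeffs, truth$grid, dose_index, covariates, truth$gamma)
}

#' True personalized MTD
#'
#' The dose whose true toxicity probability, given the patient's covariates,
#' is closest to the target rate; ties go to the highest dose.
#'
#' @param truth A [scenario_truth()].
#' @param covariates Covariate vector (empty for no-covariate scenarios).
#' @return Integer dose index.
#' @export
true_pmtd <- function(truth, covariates = numeric()) {
  p <- true_prob(truth, seq_len(n_doses(truth$grid)), covariates)
  select_dose(p, truth$tau)
}
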