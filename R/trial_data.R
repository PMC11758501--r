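#' Accumulated per-patient trial data
#'
#' @param dose_index Integer vector of assigned dose levels.
#' @param y Binary DLT outcomes (0/1), same length.
#' @param X Covariate matrix with one row per patient (may have 0 columns).
#' @param cohort Optional integer cohort labels.
#' @return An object of class `trial_data`.
#' @export
trial_data <- function(dose_index = integer(), y = integer(),
                       X = matrix(0, length(y), 0), cohort = NULL) {
  n <- length(y)
  X <- as.matrix(X)
  stopifnot(length(dose_index) == n, nrow(X) == n)
  if (n > 0 && !all(y %in% c(0, 1))) stop("outcomes must be 0/1")
  if (n > 0 && any(dose_index < 1 | dose_index != round(dose_index)))
    stop("dose indices must be positive integers")
  if (!is.null(cohort)) stopifnot(length(cohort) == n)
  structure(list(dose_index = as.integer(dose_index), y = as.integer(y),
                 X = X, cohort = cohort, n = n),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  cat("<trial_data>", x$n, "patients,", ncol(x$X), "covariate(s),",
      sum(x$y), "DLT(s)\n")
  invisible(x)
}

# append one cohort of patients
append_cohort <- function(data, dose_index, y, X, cohort) {
  trial_data(c(data$dose_index, dose_index), c(data$y, y),
             rbind(data$X, X),
             cohort = c(data$cohort %||% integer(), rep(cohort, length(y))))
}

#' Bernoulli log likelihood of the logistic dose-toxicity model
#'
#' \eqn{\sum_i y_i \log p_i + (1-y_i)\log(1-p_i)} with \eqn{p_i} evaluated at
#' patient *i*'s dose and covariates.  Probabilities are clamped at 1e-12 to
#' keep the log finite under extreme parameter values.
#'
#' @param params List with `alpha`, `log_beta`, `gamma` (length must match
#'   the covariate columns of `data`).
#' @param data A [trial_data()].
#' @param grid A [dose_grid()].
#' @return Log likelihood (0 for empty data).
#' @export
log_likelihood <- function(params, data, grid) {
  stopifnot(inherits(data, "trial_data"), inherits(grid, "dose_grid"))
  if (data$n == 0) return(0)
  gamma <- params$gamma %||% numeric()
  if (length(gamma) != ncol(data$X))
    stop("gamma length does not match the data's covariate dimension")
  eta <- params$alpha +
    exp(params$log_beta) * log_dose_ratio(grid)[data$dose_index]
  if (length(gamma)) eta <- eta + as.numeric(data$X %*% gamma)
  p <- clamp_prob(invlogit(eta))
  sum(data$y * log(p) + (1 - data$y) * log(1 - p))
}

#' Read / write per-patient trial data as CSV
#'
#' The on-disk layout has columns `patient_id`, `cohort`, `dose_index`,
#' `dose_mg`, `x1..xp`, `dlt`.
#'
#' @param data A [trial_data()].
#' @param grid A [dose_grid()] (to record `dose_mg`).
#' @param path File path.
#' @return `write_trial_data` returns `path` invisibly; `read_trial_data`
#'   returns a [trial_data()].
#' @export
write_trial_data <- function(data, grid, path) {
  df <- data.frame(patient_id = seq_len(data$n),
                   cohort = data$cohort %||% rep(NA_integer_, data$n),
                   dose_index = data$dose_index,
                   dose_mg = grid$doses[data$dose_index])
  if (ncol(data$X) > 0) {
    Xd <- as.data.frame(data$X)
    names(Xd) <- paste0("x", seq_len(ncol(data$X)))
    df <- cbind(df, Xd)
  }
  df$dlt <- data$y
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  df <- read.csv(path)
  xc <- grep("^x[0-9]+$", names(df), value = TRUE)
  X <- as.matrix(df[, xc, drop = FALSE])
  cohort <- if (all(is.na(df$cohort))) NULL else df$cohort
  trial_data(df$dose_index, df$dlt, X, cohort = cohort)
}
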