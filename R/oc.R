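#' In-trial allocation metrics
#'
#' Percentage of enrolled patients allocated to their true personalized MTD
#' (`mtd_trial`) and to a dose strictly above it (`ov_trial`).
#'
#' @param truth A [scenario_truth()].
#' @param record A [run_trial()] record.
#' @return Named vector `c(mtd_trial, ov_trial)` in percent.
#' @export
trial_metrics <- function(truth, record) {
  data <- record$data
  true_idx <- pmtd_of_rows(truth,
                           data$X[, seq_along(truth$gamma), drop = FALSE])
  c(mtd_trial = 100 * mean(data$dose_index == true_idx),
    ov_trial = 100 * mean(data$dose_index > true_idx))
}

#' Additional-patient recommendation metrics
#'
#' Simulates `n_add` fresh patients from the scenario's covariate
#' distribution, recommends a dose for each with the trial's *final* fitted
#' model, and scores the percentage recommended their true personalized MTD
#' (`mtd_add`) and a dose strictly above it (`ov_add`).
#'
#' @param truth A [scenario_truth()].
#' @param record A [run_trial()] record (supplies the final model and, for
#'   the cchange design, the covariates it ended up including).
#' @param n_add Number of additional patients; default 100.
#' @param seed Optional integer seed.
#' @return Named vector `c(mtd_add, ov_add)` in percent.
#' @export
evaluate_additional <- function(truth, record, n_add = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- gen_covariates(truth$covariates, n_add)
  true_idx <- pmtd_of_rows(truth, X[, seq_along(truth$gamma), drop = FALSE])
  fit <- record$final_fit
  rec <- if (fit$p == 0) {
    phat <- estimate_prob_matrix(fit, matrix(0, 1, 0))[1, ]
    rep(select_dose(phat, record$design$tau), n_add)
  } else {
    select_dose_rows(
      estimate_prob_matrix(fit, X[, record$final_cols, drop = FALSE]),
      record$design$tau)
  }
  c(mtd_add = 100 * mean(rec == true_idx),
    ov_add = 100 * mean(rec > true_idx))
}

#' Aggregate per-trial metrics into an operating-characteristics table
#'
#' Within a scenario, trials are averaged arithmetically for all four
#' metrics.  The cross-scenario summary uses the *geometric* mean for the
#' MTD-allocation metrics (which penalizes designs that collapse in any one
#' scenario) and the arithmetic mean for the overdosing metrics.
#'
#' @param per_trial A list (one element per scenario) of matrices/data
#'   frames with columns `mtd_add`, `ov_add` and optionally `mtd_trial`,
#'   `ov_trial`; one row per simulated trial.
#' @param scenarios Character vector of scenario labels.
#' @return An object of class `oc_result`: a data frame of per-scenario
#'   averages with a `"summary"` row, plus attributes `n_sim` (per
#'   scenario).
#' @export
aggregate_oc <- function(per_trial, scenarios = names(per_trial)) {
  stopifnot(length(per_trial) >= 1)
  if (is.null(scenarios))
    scenarios <- paste0("scenario", seq_along(per_trial))
  rows <- lapply(per_trial, function(m) colMeans(as.matrix(m)))
  tab <- as.data.frame(do.call(rbind, rows))
  rownames(tab) <- scenarios
  geo <- function(v) {
    if (any(v == 0)) {
      warning("geometric mean over scenarios with a zero value; returning 0")
      return(0)
    }
    exp(mean(log(v)))
  }
  summary_row <- vapply(names(tab), function(col) {
    v <- tab[[col]]
    if (grepl("^mtd", col)) geo(v) else mean(v)
  }, numeric(1))
  out <- rbind(tab, summary = summary_row)
  attr(out, "n_sim") <- vapply(per_trial, function(m) nrow(as.matrix(m)),
                               numeric(1))
  class(out) <- c("oc_result", class(out))
  out
}

#' @export
print.oc_result <- function(x, ...) {
  cat("Operating characteristics (percent; summary row: geometric mean for",
      "MTD metrics, arithmetic for overdosing)\n")
  print(round(as.data.frame(x), 1))
  invisible(x)
}

# deterministic per-(scenario, trial) seed streams from one master seed
derive_seeds <- function(master_seed, n_scen, n_sim) {
  set.seed(master_seed)
  list(trial = matrix(sample.int(2^31 - 2, n_scen * n_sim), n_scen, n_sim),
       add = matrix(sample.int(2^31 - 2, n_scen * n_sim), n_scen, n_sim))
}

#' Run a full operating-characteristics study
#'
#' Simulates `n_sim` independent trials for each scenario, scores each with
#' [trial_metrics()] and [evaluate_additional()], and aggregates with
#' [aggregate_oc()].  Per-trial seeds are derived deterministically from
#' `master_seed`, so results do not depend on evaluation order.
#'
#' @param truths A list of [scenario_truth()] objects (or a single one).
#' @param design A [design_spec()].
#' @param n_sim Trials per scenario.
#' @param master_seed Integer master seed.
#' @param n_add Additional patients per trial; default 100.
#' @return An `oc_result` (see [aggregate_oc()]); failed trials (e.g.
#'   sampler errors) are dropped with a warning and the effective
#'   replicate count recorded.
#' @export
run_oc <- function(truths, design, n_sim, master_seed, n_add = 100) {
  if (inherits(truths, "scenario_truth")) truths <- list(truths)
  stopifnot(n_sim >= 1)
  seeds <- derive_seeds(master_seed, length(truths), n_sim)
  per_trial <- vector("list", length(truths))
  n_fail <- 0
  for (s in seq_along(truths)) {
    rows <- vector("list", n_sim)
    for (t in seq_len(n_sim)) {
      rows[[t]] <- tryCatch({
        rec <- run_trial(truths[[s]], design, seed = seeds$trial[s, t])
        c(evaluate_additional(truths[[s]], rec, n_add = n_add,
                              seed = seeds$add[s, t]),
          trial_metrics(truths[[s]], rec))
      }, error = function(e) {
        warning("trial failed (scenario ", s, ", replicate ", t, "): ",
                conditionMessage(e))
        NULL
      })
    }
    ok <- !vapply(rows, is.null, logical(1))
    n_fail <- n_fail + sum(!ok)
    per_trial[[s]] <- do.call(rbind, rows[ok])
  }
  names(per_trial) <- names(truths) %||%
    paste0("scenario", seq_along(truths))
  out <- aggregate_oc(per_trial)
  attr(out, "n_fail") <- n_fail
  attr(out, "master_seed") <- master_seed
  out
}

#' Hyperparameter calibration over a grid
#'
#' Reproduces the calibration protocol used to pick design hyperparameters
#' (inclusion threshold, LASSO \eqn{\delta}, spike variance): for each grid
#' value, run the full operating-characteristics study on every truth case
#' and score the value by the geometric mean of the summary `mtd_add`
#' across cases; return the argmax and the full score surface.
#'
#' @param design_factory Function mapping a grid value to a [design_spec()].
#' @param grid Numeric vector of candidate values.
#' @param truth_cases A list of scenario lists (one element per covariate
#'   case, e.g. "none", "one", "two"; each a list of [scenario_truth()]).
#' @param n_sim Trials per scenario per grid value.
#' @param master_seed Integer master seed (shared across grid values so the
#'   comparison is paired).
#' @param n_add Additional patients per trial.
#' @return List with `best` (the selected grid value), `surface` (data frame
#'   of grid value and score) and `details` (per-value, per-case
#'   `oc_result`s).
#' @export
calibrate_hyperparameter <- function(design_factory, grid, truth_cases,
                                     n_sim, master_seed, n_add = 100) {
  stopifnot(length(grid) >= 1, is.function(design_factory))
  if (inherits(truth_cases[[1]], "scenario_truth"))
    truth_cases <- list(truth_cases)
  details <- lapply(grid, function(v) {
    design <- design_factory(v)
    lapply(truth_cases, run_oc, design = design, n_sim = n_sim,
           master_seed = master_seed, n_add = n_add)
  })
  score <- vapply(details, function(case_results) {
    vals <- vapply(case_results, function(oc)
      oc["summary", "mtd_add"], numeric(1))
    exp(mean(log(pmax(vals, 1e-12))))
  }, numeric(1))
  best <- grid[which.max(score)]
  list(best = best,
       surface = data.frame(value = grid, score = score),
       details = setNames(details, paste0("value_", grid)))
}
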