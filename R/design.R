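#' Select the dose closest to the target toxicity rate
#'
#' \eqn{\mathrm{argmin}_k |\hat p_k - \tau|}, with ties resolved to the
#' *highest* dose index.  The same rule defines both the estimated and the
#' true personalized MTD.
#'
#' @param p_hat Probability vector over doses.
#' @param tau Target toxicity rate.
#' @return Integer dose index.
#' @export
select_dose <- function(p_hat, tau) {
  if (length(p_hat) == 0) stop("empty probability vector")
  if (any(!is.finite(p_hat))) stop("non-finite probabilities")
  d <- abs(p_hat - tau)
  max(which(d == min(d)))
}

# row-wise select_dose for a patients-by-doses probability matrix
select_dose_rows <- function(P, tau) {
  D <- abs(P - tau)
  mins <- do.call(pmin, as.data.frame(D))
  # ties to the highest dose: scan columns from the top
  out <- integer(nrow(P))
  for (k in rev(seq_len(ncol(P)))) {
    hit <- out == 0L & D[, k] <= mins + 1e-15
    out[hit] <- k
  }
  out
}

default_cchange <- function(kinds) {
  if (length(unique(kinds)) == 2)
    unname(c(normal = 0.1, binary = 0.3)[kinds])
  else if (all(kinds == "normal")) rep(0.2, length(kinds))
  else rep(0.3, length(kinds))
}

#' Dose-finding design configuration
#'
#' @param method One of `"blrm"` (covariate-free reference design),
#'   `"blrmc"` (covariates always in the model, flat-normal prior),
#'   `"cchange"` (trial starts covariate-free; each candidate covariate is
#'   added permanently once the allocation-change criterion exceeds its
#'   threshold), `"lasso"` (Bayesian-LASSO prior on the coefficients) or
#'   `"spikeslab"`.
#' @param covariate_kinds Kinds (`"normal"`/`"binary"`) of the covariates the
#'   *model* may use, in the order of the corresponding data columns chosen
#'   by `covariate_cols`.  Empty for `"blrm"`.
#' @param covariate_cols Columns of the generated covariate matrix the model
#'   uses; defaults to the first `length(covariate_kinds)` columns.
#' @param tau Target toxicity rate; default 0.25.
#' @param n_total Total sample size; default 30.
#' @param cohort_size Patients per cohort; default 3. Must divide `n_total`.
#' @param start_dose Dose index for the first cohort; default 1 (the lowest
#'   dose).
#' @param cchange_thresholds Per-covariate inclusion thresholds for
#'   `"cchange"` (strict `>` comparison).  Defaults to the calibrated
#'   values: 0.2 per covariate when all candidates are continuous, and
#'   `(normal 0.1, binary 0.3)` for mixed candidates.
#' @param prior Optional [prior_spec()] override; by default it is built
#'   from `method` and `covariate_kinds` with the calibrated
#'   hyperparameters.
#' @param engine,settings Posterior engine and knobs, passed to
#'   [fit_posterior()].
#' @param no_skip If `TRUE`, escalation is restricted to one level above the
#'   highest dose already given (off by default: the allocation rule itself
#'   imposes no skipping restriction).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(method = c("blrm", "blrmc", "cchange", "lasso",
                                   "spikeslab"),
                        covariate_kinds = character(),
                        covariate_cols = seq_along(covariate_kinds),
                        tau = 0.25, n_total = 30, cohort_size = 3,
                        start_dose = 1, cchange_thresholds = NULL,
                        prior = NULL, engine = "auto", settings = list(),
                        no_skip = FALSE) {
  method <- match.arg(method)
  stopifnot(n_total %% cohort_size == 0, tau > 0, tau < 1, start_dose >= 1)
  covariate_kinds <- as.character(covariate_kinds)
  p <- length(covariate_kinds)
  if (method == "blrm" && p > 0)
    stop("the BLRM design does not use covariates")
  if (method != "blrm" && p == 0)
    stop("method '", method, "' needs at least one candidate covariate")
  stopifnot(length(covariate_cols) == p)
  if (is.null(prior)) {
    type <- switch(method, blrm = "none", blrmc = "normal",
                   cchange = "normal", lasso = "lasso",
                   spikeslab = "spikeslab")
    prior <- prior_spec(covariate_kinds, type = type)
  }
  if (method == "cchange") {
    if (is.null(cchange_thresholds))
      cchange_thresholds <- default_cchange(covariate_kinds)
    # thresholds outside (0,1) are allowed for boundary behaviour: 0 forces
    # inclusion at the first disagreement, > 1 disables inclusion entirely
    stopifnot(length(cchange_thresholds) == p, all(cchange_thresholds >= 0))
  }
  structure(list(method = method, covariate_kinds = covariate_kinds,
                 covariate_cols = as.integer(covariate_cols), tau = tau,
                 n_total = as.integer(n_total),
                 cohort_size = as.integer(cohort_size),
                 start_dose = as.integer(start_dose),
                 cchange_thresholds = cchange_thresholds, prior = prior,
                 engine = engine, settings = settings,
                 no_skip = isTRUE(no_skip)),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat("<design_spec>", toupper(x$method), "| N =", x$n_total, "in cohorts of",
      x$cohort_size, "| tau =", x$tau, "\n")
  if (length(x$covariate_kinds))
    cat("  model covariates:", paste(x$covariate_kinds, collapse = ", "),
        "\n")
  invisible(x)
}

#' Allocate a cohort of patients
#'
#' Covariate-free models give every cohort member the single dose minimizing
#' \eqn{|\hat p(d) - \tau|}; covariate-aware models allocate each patient to
#' their estimated personalized MTD \eqn{\mathrm{argmin}_k
#' |\hat p(d_k \mid x_i) - \tau|}.
#'
#' @param post A `posterior_estimate`.
#' @param cohort_covariates Covariate matrix for the cohort (columns aligned
#'   with the fitted model's covariates).
#' @param tau Target toxicity rate.
#' @param covariate_aware If `FALSE`, one shared dose for the cohort.
#' @return Integer dose index per patient.
#' @export
allocate_cohort <- function(post, cohort_covariates, tau,
                            covariate_aware = post$p > 0) {
  n <- nrow(cohort_covariates)
  if (!covariate_aware) {
    phat <- estimate_prob_matrix(post, matrix(0, 1, 0))[1, ]
    return(rep(select_dose(phat, tau), n))
  }
  select_dose_rows(estimate_prob_matrix(post, cohort_covariates), tau)
}

#' Proportion of patients whose recommended dose changes with a covariate
#'
#' The inclusion statistic \eqn{\mathcal{R} = n^{-1}\sum_i
#' 1\{d_{(i,n)}^{without} \ne d_{(i,n)}^{with}\}}: both models are refitted
#' on the same `n` enrolled patients, each patient's recommended dose is
#' computed from their stored covariates under each fit, and the proportion
#' of disagreements is returned.
#'
#' @param data A [trial_data()] with `n >= 1`.
#' @param post_without,post_with Posterior fits of the two models on `data`.
#' @param tau Target toxicity rate.
#' @param cols_without,cols_with Columns of `data$X` feeding each model
#'   (defaults: the first `p` columns of each fit).
#' @return Proportion in `[0, 1]`.
#' @export
cchange_ratio <- function(data, post_without, post_with, tau,
                          cols_without = seq_len(post_without$p),
                          cols_with = seq_len(post_with$p)) {
  if (data$n == 0) stop("cchange ratio is undefined for empty data")
  rec_wo <- select_dose_rows(
    estimate_prob_matrix(post_without,
                         data$X[, cols_without, drop = FALSE]), tau)
  rec_wi <- select_dose_rows(
    estimate_prob_matrix(post_with,
                         data$X[, cols_with, drop = FALSE]), tau)
  mean(rec_wo != rec_wi)
}

#' Inclusion state bookkeeping for the cchange design
#'
#' Covariate `j` becomes included when its ratio strictly exceeds its
#' threshold; once included it remains so for the rest of the trial.
#'
#' @param state List with `included` (logical per covariate) and `history`
#'   (list of per-cohort ratio vectors).
#' @param ratios Per-covariate \eqn{\mathcal{R}} values (`NA` for covariates
#'   not evaluated this cohort, e.g. already-included ones).
#' @param thresholds Per-covariate thresholds.
#' @return Updated state.
#' @export
update_inclusion <- function(state, ratios, thresholds) {
  stopifnot(length(ratios) == length(state$included),
            length(thresholds) == length(state$included))
  newly <- !state$included & !is.na(ratios) & ratios > thresholds
  state$included <- state$included | newly
  state$history <- c(state$history, list(ratios))
  state
}

new_inclusion_state <- function(p) list(included = rep(FALSE, p),
                                        history = list())

# evaluate expr without disturbing the ambient RNG stream
with_preserved_rng <- function(expr) {
  if (!exists(".Random.seed", globalenv())) runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  expr
}

# prior for the cchange working model on a given included subset
subset_prior <- function(design, idx) {
  if (length(idx) == 0)
    prior_spec(mean = design$prior$mean, cov = design$prior$cov)
  else
    prior_spec(design$covariate_kinds[idx], type = "normal",
               mean = design$prior$mean, cov = design$prior$cov)
}

fit_model <- function(prior, data, cols, grid, design, fit_seed, quad_cache) {
  sub <- trial_data(data$dose_index, data$y,
                    data$X[, cols, drop = FALSE], cohort = data$cohort)
  settings <- design$settings
  if (n_model_covariates(prior) == 0 && !is.null(quad_cache))
    settings$engine_cache <- quad_cache
  with_preserved_rng(
    fit_posterior(prior, sub, grid, engine = design$engine,
                  settings = settings, seed = fit_seed))
}

#' Simulate one sequential dose-finding trial
#'
#' Runs cohorts of `cohort_size` patients until `n_total`: covariates are
#' drawn from the scenario's covariate distribution, doses are allocated
#' under the design's current model (first cohort at the starting dose),
#' binary DLT outcomes are drawn from the *true* model, the posterior is
#' refitted, and — for the `"cchange"` method — the inclusion criterion is
#' applied after every cohort.  The covariate-generation and outcome RNG
#' stream is kept separate from the model-fitting stream, so two designs
#' sharing a seed see identical patients whenever their allocations agree.
#'
#' @param truth A [scenario_truth()].
#' @param design A [design_spec()] whose `covariate_cols` are valid columns
#'   of the scenario's covariate matrix.
#' @param seed Integer seed; the trial is reproducible bit-for-bit from
#'   `(truth, design, seed)`.
#' @return An object of class `trial_record`: the accumulated
#'   [trial_data()], per-cohort allocations and posterior summaries, the
#'   inclusion state and history, the final fitted model and the covariate
#'   columns it uses.
#' @export
run_trial <- function(truth, design, seed) {
  stopifnot(inherits(truth, "scenario_truth"), inherits(design, "design_spec"))
  p_truth <- n_covariates(truth$covariates)
  if (length(design$covariate_cols) &&
      max(design$covariate_cols) > p_truth)
    stop("design uses covariate columns the scenario does not generate")
  grid <- truth$grid
  set.seed(seed)
  fit_seed_base <- sample.int(2^31 - 2, 1)
  p_model <- length(design$covariate_kinds)
  n_cohorts <- design$n_total %/% design$cohort_size
  quad_cache <- if (design$engine %in% c("auto", "quadrature") &&
                    design$method %in% c("blrm", "cchange"))
    quad_engine(subset_prior(design, integer(0)), grid,
                nodes = design$settings$nodes %||% 201,
                span = design$settings$span %||% 6)
  else NULL
  # cchange bookkeeping
  state <- new_inclusion_state(p_model)
  data <- trial_data(X = matrix(0, 0, p_truth))
  fit <- NULL            # model used for the next allocation
  fit_cols <- integer()  # columns of X that model consumes
  allocations <- vector("list", n_cohorts)
  summaries <- vector("list", n_cohorts)
  model_used <- character(0)
  fit_counter <- 0L
  next_fit_seed <- function() {
    fit_counter <<- fit_counter + 1L
    (fit_seed_base + fit_counter) %% (2^31 - 1) + 1
  }

  current_model_name <- function() {
    if (design$method != "cchange") design$method
    else if (!any(state$included)) "blrm"
    else paste0("blrmc[", paste(which(state$included), collapse = ","), "]")
  }

  for (co in seq_len(n_cohorts)) {
    Xc <- gen_covariates(truth$covariates, design$cohort_size)
    if (co == 1) {
      doses <- rep(design$start_dose, design$cohort_size)
    } else {
      doses <- allocate_cohort(fit, Xc[, fit_cols, drop = FALSE],
                               design$tau, covariate_aware = fit$p > 0)
      if (design$no_skip) doses <- pmin(doses, max(data$dose_index) + 1L)
    }
    check_dose_index(grid, doses)
    p_i <- vapply(seq_len(design$cohort_size), function(i)
      true_prob(truth, doses[i],
                Xc[i, seq_along(truth$gamma), drop = TRUE]), numeric(1))
    y <- rbinom(design$cohort_size, 1, p_i)
    model_used <- c(model_used, rep(current_model_name(),
                                    design$cohort_size))
    data <- append_cohort(data, doses, y, Xc, co)

    # refit the working model (and, for cchange, evaluate the criterion)
    if (design$method == "cchange") {
      base_idx <- which(state$included)
      base_cols <- design$covariate_cols[base_idx]
      base_fit <- fit_model(subset_prior(design, base_idx), data, base_cols,
                            grid, design, next_fit_seed(), quad_cache)
      ratios <- rep(NA_real_, p_model)
      cand_fits <- list()
      for (j in which(!state$included)) {
        idx_j <- sort(c(base_idx, j))
        cols_j <- design$covariate_cols[idx_j]
        fit_j <- fit_model(subset_prior(design, idx_j), data, cols_j,
                           grid, design, next_fit_seed(), quad_cache)
        cand_fits[[as.character(j)]] <- list(fit = fit_j, cols = cols_j)
        ratios[j] <- cchange_ratio(data, base_fit, fit_j, design$tau,
                                   cols_without = base_cols,
                                   cols_with = cols_j)
      }
      state <- update_inclusion(state, ratios, design$cchange_thresholds)
      new_idx <- which(state$included)
      if (identical(new_idx, base_idx)) {
        fit <- base_fit; fit_cols <- base_cols
      } else if (length(new_idx) == 1 && length(base_idx) == 0 &&
                 !is.null(cand_fits[[as.character(new_idx)]])) {
        fit <- cand_fits[[as.character(new_idx)]]$fit
        fit_cols <- cand_fits[[as.character(new_idx)]]$cols
      } else {
        fit_cols <- design$covariate_cols[new_idx]
        fit <- fit_model(subset_prior(design, new_idx), data, fit_cols,
                         grid, design, next_fit_seed(), quad_cache)
      }
    } else {
      fit_cols <- design$covariate_cols
      fit <- fit_model(design$prior, data, fit_cols, grid, design,
                       next_fit_seed(), quad_cache)
    }
    allocations[[co]] <- doses
    summaries[[co]] <- list(
      phat_x0 = estimate_prob_matrix(fit,
        matrix(0, 1, fit$p))[1, ],
      model = current_model_name(),
      ratios = if (design$method == "cchange") state$history[[co]] else NULL,
      max_rhat = fit$diagnostics$max_rhat %||% NA_real_)
  }
  structure(list(data = data, allocations = allocations,
                 summaries = summaries, inclusion = state,
                 model_used = model_used, final_fit = fit,
                 final_cols = fit_cols, design = design, seed = seed,
                 n_cohorts = n_cohorts),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat("<trial_record>", x$data$n, "patients in", x$n_cohorts,
      "cohorts | method:", x$design$method, "\n")
  cat("  allocations:",
      paste(vapply(x$allocations, function(d) paste(d, collapse = ""),
                   character(1)), collapse = " | "), "\n")
  if (x$design$method == "cchange")
    cat("  included covariates:",
        if (any(x$inclusion$included))
          paste(which(x$inclusion$included), collapse = ", ") else "none",
        "\n")
  invisible(x)
}
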