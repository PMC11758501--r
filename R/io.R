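# ---- scenario configuration files -----------------------------------------

#' Read scenario definitions from a JSON file
#'
#' Each scenario entry either gives model coefficients directly
#' (`coefficients`) or target marginal probabilities (`target_marginals`),
#' in which case [calibrate_truth()] is invoked.  Common keys: `family`,
#' `doses`, `reference_dose`, `gamma`, `covariates` (list of
#' `kind`/`mean`/`sd`/`prob`), `correlation`, `tau`.  A bundled fixture with
#' the five benchmark marginal rows ships as
#' `system.file("extdata", "benchmark_scenarios.json",
#' package = "pmtddesign")`.
#'
#' @param path Path to a JSON scenario file.
#' @return Named list of [scenario_truth()] objects.
#' @export
read_scenarios <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  scen <- cfg$scenarios %||% cfg
  out <- lapply(scen, scenario_from_config)
  names(out) <- vapply(seq_along(scen), function(i)
    scen[[i]]$name %||% paste0("scenario", i), character(1))
  out
}

scenario_from_config <- function(s) {
  grid <- dose_grid(unlist(s$doses), s$reference_dose %||% 5)
  cov <- covariates_from_config(s$covariates, s$correlation)
  gamma <- as.numeric(unlist(s$gamma %||% numeric()))
  tau <- s$tau %||% 0.25
  family <- s$family %||% "logistic"
  if (!is.null(s$coefficients))
    scenario_truth(family, grid, unlist(s$coefficients), gamma = gamma,
                   covariates = cov, tau = tau)
  else if (!is.null(s$target_marginals))
    calibrate_truth(unlist(s$target_marginals), family, grid,
                    fixed_gamma = gamma, covariates = cov, tau = tau)
  else stop("scenario needs either 'coefficients' or 'target_marginals'")
}

covariates_from_config <- function(desc, correlation = NULL) {
  if (is.null(desc) || length(desc) == 0) return(covariate_spec())
  kinds <- vapply(desc, function(d) d$kind, character(1))
  covariate_spec(kinds,
                 means = vapply(desc, function(d) d$mean %||% 0, numeric(1)),
                 sds = vapply(desc, function(d) d$sd %||% 1, numeric(1)),
                 probs = vapply(desc, function(d) d$prob %||% 0.5,
                                numeric(1)),
                 correlation = if (!is.null(correlation))
                   matrix(unlist(correlation),
                          nrow = sum(kinds == "normal")) else NULL)
}

#' Load scenario coefficients from a supplementary CSV
#'
#' Ingests a plain CSV with columns `scenario`, `alpha`, `beta` and optional
#' `gamma1`, `gamma2`, ... giving the exact generating coefficients of
#' covariate scenarios (the published supplementary coefficient table, if
#' available to the user).
#'
#' @param path CSV path.
#' @param grid A [dose_grid()]; defaults to the benchmark grid.
#' @param covariates A [covariate_spec()] describing the gamma columns.
#' @param tau Target rate.
#' @return Named list of [scenario_truth()] objects.
#' @export
read_supplementary_coeffs <- function(path,
                                      grid = dose_grid(c(1, 3, 5, 7, 9), 5),
                                      covariates = NULL, tau = 0.25) {
  df <- read.csv(path)
  stopifnot(all(c("scenario", "alpha", "beta") %in% names(df)))
  gc <- grep("^gamma[0-9]+$", names(df), value = TRUE)
  if (is.null(covariates))
    covariates <- covariate_spec(rep("normal", length(gc)))
  out <- lapply(seq_len(nrow(df)), function(i)
    scenario_truth("logistic", grid, c(df$alpha[i], df$beta[i]),
                   gamma = as.numeric(df[i, gc]), covariates = covariates,
                   tau = tau))
  names(out) <- as.character(df$scenario)
  out
}

# ---- design configuration --------------------------------------------------

#' Build a design from a configuration list
#'
#' Accepts the parsed JSON design block: `method`, `covariate_kinds`,
#' `covariate_cols`, `tau`, `n_total`, `cohort_size`, `start_dose`,
#' `cchange_thresholds`, `engine`, `settings`, and optional prior
#' hyperparameter overrides (`sigma2`, `delta`, `spike_var`, `slab_var`,
#' `b1`, `b2`, `prior_mean`, `prior_cov`).
#'
#' @param cfg A named list (or path to a JSON file).
#' @return A [design_spec()].
#' @export
design_from_config <- function(cfg) {
  if (is.character(cfg))
    cfg <- jsonlite::read_json(cfg, simplifyVector = TRUE)
  kinds <- as.character(unlist(cfg$covariate_kinds %||% character()))
  type <- switch(cfg$method, blrm = "none", blrmc = "normal",
                 cchange = "normal", lasso = "lasso",
                 spikeslab = "spikeslab",
                 stop("unknown method: ", cfg$method))
  prior_args <- list(covariate_kinds = kinds, type = type)
  if (!is.null(cfg$prior_mean)) prior_args$mean <- unlist(cfg$prior_mean)
  if (!is.null(cfg$prior_cov))
    prior_args$cov <- matrix(unlist(cfg$prior_cov), 2, 2)
  for (k in c("sigma2", "slab_var", "b1", "b2"))
    if (!is.null(cfg[[k]])) prior_args[[k]] <- cfg[[k]]
  for (k in c("delta", "spike_var"))
    if (!is.null(cfg[[k]])) prior_args[[k]] <- unlist(cfg[[k]])
  prior <- do.call(prior_spec, prior_args)
  design_spec(method = cfg$method, covariate_kinds = kinds,
              covariate_cols = unlist(cfg$covariate_cols %||%
                                        seq_along(kinds)),
              tau = cfg$tau %||% 0.25, n_total = cfg$n_total %||% 30,
              cohort_size = cfg$cohort_size %||% 3,
              start_dose = cfg$start_dose %||% 1,
              cchange_thresholds = unlist(cfg$cchange_thresholds %||%
                                            NULL),
              prior = prior, engine = cfg$engine %||% "auto",
              settings = cfg$settings %||% list(),
              no_skip = isTRUE(cfg$no_skip))
}

# ---- output writers --------------------------------------------------------

#' Write an operating-characteristics table
#'
#' `path_wide` receives the report layout (one row, scenario columns for
#' `mtd_add` then its summary, the same for `ov_add`); `path_long` receives
#' a long-format table (scenario, metric, value) for machine reading.
#'
#' @param oc An `oc_result`.
#' @param path_wide,path_long Output CSV paths (`NULL` to skip either).
#' @param label Model label for the wide row.
#' @return Invisibly, the wide-format data frame.
#' @export
write_oc_result <- function(oc, path_wide = NULL, path_long = NULL,
                            label = "model") {
  df <- as.data.frame(oc)
  scen <- setdiff(rownames(df), "summary")
  wide <- data.frame(model = label)
  for (s in scen) wide[[paste0("mtd_add_", s)]] <- df[s, "mtd_add"]
  wide$mtd_add_mean <- df["summary", "mtd_add"]
  for (s in scen) wide[[paste0("ov_add_", s)]] <- df[s, "ov_add"]
  wide$ov_add_mean <- df["summary", "ov_add"]
  if (!is.null(path_wide)) write.csv(wide, path_wide, row.names = FALSE)
  if (!is.null(path_long)) {
    long <- do.call(rbind, lapply(rownames(df), function(s)
      data.frame(scenario = s, metric = names(df),
                 value = as.numeric(df[s, ]))))
    write.csv(long, path_long, row.names = FALSE)
  }
  invisible(wide)
}

# polynomial rolling hash of a serialized config (provenance stamp only)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                      digits = NA))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_manifest <- function(path, cfg, extra = list()) {
  jsonlite::write_json(
    c(list(config = cfg, config_hash = config_hash(cfg),
           package_version = as.character(utils::packageVersion("pmtddesign")),
           timestamp = format(Sys.time(), tz = "UTC")),
      extra),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
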