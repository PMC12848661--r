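#' Build model data with a Markov-probe covariate
#'
#' Converts an event history into the counting-process long data used by the
#' recurrent-event models for the home->hospital transition. Only at-home
#' intervals are kept: while in hospital, subjects are not at risk for
#' (another) hospitalization. Each interval carries the treatment covariate
#' and a time-varying covariate probing the Markov assumption:
#' `prev_count`, the number of completed hospitalizations before the
#' interval starts, or `entry_time`, the start of the interval (= the time
#' of entry into the current at-home state, in days). Both are always
#' returned; `kind` only validates the request. A significant effect of
#' either covariate indicates a violation of the Markov property.
#'
#' @param history An `event_history`.
#' @param kind `"prev_count"` or `"entry_time"`.
#' @return Data frame with columns `id`, `start`, `stop`, `status`
#'   (1 = hospital admission at `stop`), `Z`, `prev_count`, `entry_time`.
#' @export
augment_markov_covariate <- function(history, kind = c("prev_count", "entry_time")) {
  match.arg(kind)
  df <- as.data.frame(history)
  df <- df[order(df$id, df$start), , drop = FALSE]
  prev <- prev_admissions(df)
  home <- df$from == 0L
  out <- data.frame(id = df$id[home],
                    start = df$start[home],
                    stop = df$stop[home],
                    status = as.integer(df$status[home] == 1L & df$to[home] == 1L),
                    Z = df$Z[home],
                    prev_count = prev[home],
                    entry_time = df$start[home])
  rownames(out) <- NULL
  out
}

#' Fit the scenario's analysis model to one dataset
#'
#' Applies the model mapping of the simulation study: the Andersen-Gill
#' model for the illness-death scenarios (Markov probe: number of previous
#' hospitalizations) and the Prentice-Williams-Peterson model, stratified
#' by the number of previous hospitalizations on the total-time scale, for
#' the progressive scenarios (Markov probe: entry time into the current
#' at-home state, in days). `model1` includes treatment plus the Markov
#' covariate; `model2` includes treatment only.
#'
#' @param history An `event_history`.
#' @param family `"idm"` (Andersen-Gill) or `"progressive"`
#'   (Prentice-Williams-Peterson); defaults to the history's structure tag.
#' @param variant `"model1"` or `"model2"`.
#' @return A `semiparam_fit`.
#' @export
fit_scenario_model <- function(history, family = NULL,
                               variant = c("model1", "model2")) {
  variant <- match.arg(variant)
  if (is.null(family)) family <- attr(history, "structure")
  family <- match.arg(family, c("idm", "progressive"))
  probe <- if (family == "idm") "prev_count" else "entry_time"
  dat <- augment_markov_covariate(history, probe)
  covs <- if (variant == "model1") c("Z", probe) else "Z"
  strata <- if (family == "progressive") "prev_count" else NULL
  cox_fit(dat, covariates = covs, strata = strata)
}

#' Replicated Wald rejection counts for one scenario
#'
#' Simulates `R` datasets under a scenario, fits the mapped model
#' ([fit_scenario_model()]) with robust standard errors, Wald-tests every
#' covariate at level `alpha`, and counts rejections. Replications with a
#' non-converged or monotone-likelihood fit are counted as non-rejections
#' and reported in the `failures` column, never silently dropped. The
#' result is deterministic given `(id, variant, R, seed)`.
#'
#' @param id Scenario id (1-9).
#' @param variant `"model1"` (treatment + Markov covariate) or `"model2"`
#'   (treatment only).
#' @param R Number of replications.
#' @param seed Master seed.
#' @param alternative If `TRUE` simulate under the treatment alternative
#'   (hazard ratio 0.85 on home->hospital).
#' @param alpha Significance level (default 0.05).
#' @param n Subjects per dataset (default 600).
#' @param variance Variance used for the Wald tests (default robust).
#' @return Data frame of class `rejection_summary`: one row per covariate
#'   with columns `scenario`, `model`, `variant`, `covariate`,
#'   `rejections`, `R`, `failures`, `alpha`.
#' @export
run_scenario <- function(id, variant = c("model1", "model2"), R, seed = 1L,
                         alternative = FALSE, alpha = 0.05, n = 600L,
                         variance = c("robust", "model")) {
  variant <- match.arg(variant)
  variance <- match.arg(variance)
  if (R <= 0) stop("`R` must be positive")
  config <- scenario_config(id, n = n, alternative = alternative)
  family <- config$structure
  probe <- if (family == "idm") "prev_count" else "entry_time"
  covs <- if (variant == "model1") c("Z", probe) else "Z"
  rej <- setNames(numeric(length(covs)), covs)
  failures <- 0L
  for (r in seq_len(R)) {
    h <- simulate_dataset(config, rep = r, seed = seed)
    fit <- fit_scenario_model(h, family, variant)
    if (!fit$converged || fit$monotone) {
      failures <- failures + 1L
      next
    }
    for (cv in covs) {
      if (wald_test(fit, cv, variance = variance)$p < alpha) {
        rej[cv] <- rej[cv] + 1
      }
    }
  }
  out <- data.frame(scenario = id,
                    model = if (family == "idm") "AG" else "PWP",
                    variant = variant,
                    covariate = covs,
                    rejections = as.integer(rej),
                    R = as.integer(R),
                    failures = failures,
                    alpha = alpha,
                    row.names = NULL)
  class(out) <- c("rejection_summary", "data.frame")
  out
}

#' Full null-scenario rejection grid
#'
#' Runs [run_scenario()] for scenarios 1-9 under the null of no treatment
#' effect, for both model variants, and lays the rejection counts out as
#' one row per scenario: the Markov-covariate and treatment rejections of
#' model 1 and the treatment rejections of model 2.
#'
#' @param R Replications per scenario.
#' @param seed Master seed.
#' @param scenarios Scenario ids to include (default 1-9).
#' @param n Subjects per dataset.
#' @return Data frame with columns `scenario`, `model`, `markov_covariate`,
#'   `markov_rejections`, `treatment_rejections_m1`,
#'   `treatment_rejections_m2`, `R`.
#' @export
table_rejections <- function(R, seed = 1L, scenarios = 1:9, n = 600L) {
  rows <- lapply(scenarios, function(id) {
    m1 <- run_scenario(id, "model1", R, seed, n = n)
    m2 <- run_scenario(id, "model2", R, seed, n = n)
    probe <- setdiff(m1$covariate, "Z")
    data.frame(scenario = id,
               model = m1$model[1L],
               markov_covariate = probe,
               markov_rejections = m1$rejections[m1$covariate == probe],
               treatment_rejections_m1 = m1$rejections[m1$covariate == "Z"],
               treatment_rejections_m2 = m2$rejections[m2$covariate == "Z"],
               failures = m1$failures[1L] + m2$failures[1L],
               R = R)
  })
  do.call(rbind, rows)
}

#' Treatment power under the hazard-ratio 0.85 alternative
#'
#' Re-runs the scenario grid with the treated arm's home->hospital hazard
#' multiplied by exp(-0.1625) and counts treatment rejections (model 2:
#' treatment only).
#'
#' @inheritParams table_rejections
#' @return Data frame with one row per scenario: `scenario`, `model`,
#'   `rejections`, `R`, `failures`.
#' @export
power_run <- function(R, seed = 1L, scenarios = 1:9, n = 600L) {
  rows <- lapply(scenarios, function(id) {
    m <- run_scenario(id, "model2", R, seed, alternative = TRUE, n = n)
    data.frame(scenario = id, model = m$model[1L],
               rejections = m$rejections[m$covariate == "Z"],
               R = R, failures = m$failures[1L])
  })
  do.call(rbind, rows)
}

#' @importFrom stats setNames
NULL
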