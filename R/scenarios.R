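#' Simulation scenario configuration
#'
#' Defines the data-generating mechanism for one simulation scenario of a
#' randomized two-arm trial with recurrent hospitalizations and death. The
#' nine scenarios cross the model structure (illness-death with recovery vs.
#' progressive, i.e. event-count dependent hazards), a gamma frailty that
#' destroys the Markov property, and the censoring mechanism (random
#' exponential vs. state-dependent competing-risk censoring); scenario 9 is
#' a progressive model whose hazards additionally grow with the entry time
#' into the current state.
#'
#' Baseline per-day transition hazards are 0.002 (home->hospital), 0.0007
#' (home->death), 0.004 (hospital->home) and 0.00075 (hospital->death;
#' 0.0011 in scenario 9). In progressive scenarios every transition hazard
#' is multiplied by `(1 + 0.1 * number of previous states)`. The frailty is
#' a subject-level multiplier L ~ Gamma(shape 2, scale 1) applied to all
#' transition hazards (never to censoring, so that censoring stays random in
#' the random-censoring scenarios). Random censoring draws a single
#' exponential(0.00045) time per subject up front; state-dependent censoring
#' adds a third competing cause with hazard
#' `0.00045 * (1 + 0.05 * number of previous states)` to every
#' non-terminal state. Under the treatment alternative the treated arm's
#' home->hospital hazard is multiplied by `exp(-0.1625)` (hazard ratio
#' 0.85).
#'
#' In scenario 9 every transition hazard is scaled by the factor
#' `entry time into the current state / 1000`; the initial state is entered
#' at time 0, where that factor would make the first sojourn infinite, so
#' the first home sojourn is drawn at the baseline rates (factor 1). See the
#' methods vignette for the rationale and the consequences of this
#' resolution.
#'
#' @param id Scenario id, 1 through 9.
#' @param n Number of subjects (default 600; must be even, split 300/300
#'   between arms by permutation).
#' @param alternative If `TRUE`, apply the treatment effect
#'   (log hazard ratio -0.1625 on the home->hospital transition of the
#'   treated arm); default is the null of no treatment difference.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(id, n = 600L, alternative = FALSE) {
  id <- as.integer(id)
  if (!id %in% 1:9) stop("unknown scenario id: ", id)
  if (n %% 2L != 0L) stop("`n` must be even (equal arms)")
  structure(list(
    id = id,
    structure = if (id <= 4L) "idm" else "progressive",
    frailty = id %in% c(2L, 4L, 6L, 8L),
    censoring = if (id %in% c(1L, 2L, 5L, 6L)) "random" else "statedep",
    entry_time_hazards = id == 9L,
    rates = c(l01 = 0.002, l02 = 0.0007, l10 = 0.004,
              l12 = if (id == 9L) 0.0011 else 0.00075),
    frailty_shape = 2, frailty_scale = 1,
    cens_rate = 0.00045, cens_factor = 0.05,
    progressive_factor = 0.1,
    trt_loghr = if (alternative) -0.1625 else 0,
    alternative = alternative,
    n = as.integer(n)
  ), class = "scenario_config")
}

#' The nine study scenarios
#'
#' @param alternative Passed to [scenario_config()].
#' @param n Subjects per dataset.
#' @return Named list of the nine `scenario_config` objects.
#' @export
scenario_catalog <- function(alternative = FALSE, n = 600L) {
  out <- lapply(1:9, scenario_config, n = n, alternative = alternative)
  names(out) <- as.character(1:9)
  out
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario %d: %s, %s, %s censoring%s%s\n", x$id,
              if (x$frailty) "non-Markov (gamma frailty)" else
                if (x$entry_time_hazards) "non-Markov (entry-time hazards)" else "Markov",
              if (x$structure == "idm") "illness-death model" else "progressive model",
              x$censoring,
              if (x$alternative) ", treatment HR 0.85" else " (null)",
              sprintf(", n = %d", x$n)))
  invisible(x)
}

#' Draw one sojourn in a nested competing-risks experiment
#'
#' Given the currently active constant cause-specific rates, draws the
#' waiting time from an exponential with the combined rate and the cause
#' from a multinomial with probabilities proportional to the rates. This is
#' the elementary building block of the simulator: event histories are
#' generated as a nested series of such competing-risks experiments.
#'
#' @param rates Non-negative per-day rates, one per competing cause; at
#'   least one must be positive.
#' @return List with `wait` (days) and `cause` (index into `rates`).
#' @export
draw_sojourn <- function(rates) {
  if (any(rates < 0)) stop("rates must be non-negative")
  total <- sum(rates)
  if (total <= 0) stop("all rates are zero: sojourn would be infinite")
  list(wait = rexp(1L, total),
       cause = sample.int(length(rates), 1L, prob = rates))
}

#' Simulate one subject's event list
#'
#' Generates alternating home/hospital sojourns by nested competing-risks
#' draws with the state-, event-count-, frailty-, arm- and (scenario 9)
#' entry-time-adjusted rates, until death or censoring. Under random
#' censoring a single censoring time is drawn up front and the path is
#' truncated if it is reached before death; under state-dependent censoring,
#' censoring is a third competing cause in every nested experiment. Hospital
#' sojourns are drawn on the waiting (clock-reset) timescale; with constant
#' rates this is equivalent to calendar-time simulation.
#'
#' @param config A [scenario_config()].
#' @param id Subject id.
#' @param arm Treatment arm (0 control, 1 treated).
#' @param frailty Subject-level hazard multiplier (1 = none).
#' @return Data frame of this subject's records.
#' @export
simulate_subject <- function(config, id, arm, frailty = 1) {
  r <- simulate_subject_core(config, arm, frailty)
  data.frame(id = id, from = r$from, to = r$to, start = r$start,
             stop = r$stop, status = as.integer(!is.na(r$to)), Z = arm)
}

## inner loop kept free of data-frame overhead: returns parallel vectors
simulate_subject_core <- function(config, arm, frailty = 1) {
  rt <- config$rates
  hr <- exp(config$trt_loghr * arm)
  random_cens <- config$censoring == "random"
  cens_time <- if (random_cens) rexp(1L, config$cens_rate) else Inf
  t <- 0; state <- 0L; k <- 0L; entry <- 0
  from <- integer(8L); to <- integer(8L)
  start <- numeric(8L); stop_ <- numeric(8L); m <- 0L
  grow <- function(v) c(v, v)  # double capacity; tail is overwritten before use
  repeat {
    fac <- frailty
    if (config$structure == "progressive") {
      fac <- fac * (1 + config$progressive_factor * k)
    }
    if (config$entry_time_hazards && entry > 0) fac <- fac * entry / 1000
    r <- if (state == 0L) c(rt[["l01"]] * hr, rt[["l02"]]) else
      c(rt[["l10"]], rt[["l12"]])
    r <- r * fac
    cr <- if (random_cens) 0 else config$cens_rate * (1 + config$cens_factor * k)
    d <- draw_sojourn(c(r, cr))
    tnew <- t + d$wait
    if (m == length(from)) {
      from <- grow(from); to <- grow(to); start <- grow(start); stop_ <- grow(stop_)
    }
    m <- m + 1L
    from[m] <- state; start[m] <- t
    if (tnew > cens_time) {            # random censoring reached first
      to[m] <- NA_integer_; stop_[m] <- cens_time
      break
    }
    stop_[m] <- tnew
    if (d$cause == 3L) {               # state-dependent censoring
      to[m] <- NA_integer_
      break
    }
    if (state == 0L) {
      if (d$cause == 1L) { to[m] <- 1L; state <- 1L } else { to[m] <- 2L; break }
    } else {
      if (d$cause == 1L) { to[m] <- 0L; state <- 0L } else { to[m] <- 2L; break }
    }
    k <- k + 1L
    t <- tnew
    entry <- tnew
  }
  idx <- seq_len(m)
  list(from = from[idx], to = to[idx], start = start[idx], stop = stop_[idx])
}

#' Simulate a complete trial dataset
#'
#' Simulates `config$n` subjects (half per arm, assigned by permutation)
#' under the given scenario. The random-number stream is derived
#' deterministically from `(seed, scenario id, rep)`, so individual
#' replications can be reproduced in isolation and results do not depend on
#' scheduling.
#'
#' @param config A [scenario_config()].
#' @param rep Replication index (>= 1).
#' @param seed Master seed (integer).
#' @return An `event_history` with the treatment covariate `Z`.
#' @export
simulate_dataset <- function(config, rep = 1L, seed = 1L) {
  set.seed(derive_stream_seed(seed, config, rep))
  n <- config$n
  arm <- sample(rep(0:1, each = n %/% 2L))
  fr <- if (config$frailty) {
    rgamma(n, shape = config$frailty_shape, scale = config$frailty_scale)
  } else rep(1, n)
  recs <- vector("list", n)
  for (i in seq_len(n)) recs[[i]] <- simulate_subject_core(config, arm[i], fr[i])
  len <- vapply(recs, function(r) length(r$from), 1L)
  df <- data.frame(
    id = rep.int(seq_len(n), len),
    from = unlist(lapply(recs, `[[`, "from"), use.names = FALSE),
    to = unlist(lapply(recs, `[[`, "to"), use.names = FALSE),
    start = unlist(lapply(recs, `[[`, "start"), use.names = FALSE),
    stop = unlist(lapply(recs, `[[`, "stop"), use.names = FALSE))
  df$status <- as.integer(!is.na(df$to))
  df$Z <- rep.int(arm, len)
  new_event_history(df, config$structure)
}

## deterministic per-(scenario, rep) substream seed below 2^31
derive_stream_seed <- function(seed, config, rep) {
  key <- config$id + if (isTRUE(config$alternative)) 50L else 0L
  as.integer((abs(as.numeric(seed)) * 48271 + key * 1299721 + rep * 7919) %%
               2147483563)
}
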