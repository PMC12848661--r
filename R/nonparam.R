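#' Nelson-Aalen estimator of a cumulative transition hazard
#'
#' Estimates the cumulative hazard (in a Markov model) or the cumulative
#' partly conditional transition rate (in a non-Markov model with random
#' censoring) of the transition `from -> to` as the cumulative sum of
#' (number of observed `from -> to` transitions at t) / (number of subjects
#' in `from` just prior to t) over the observed transition times. Risk sets
#' use the predictable left-limit convention; censored intervals contribute
#' risk time only; ties across subjects at a transition time are processed
#' as a single jump with the summed count.
#'
#' @param history An `event_history` (or any record data frame with columns
#'   `from`, `to`, `start`, `stop`, `status`).
#' @param from,to State codes of the transition.
#' @return A [step_function()] with an attribute `n_events`.
#' @export
nelson_aalen <- function(history, from, to) {
  h <- history[history$from == from, , drop = FALSE]
  ev <- h$stop[h$status == 1L & !is.na(h$to) & h$to == to]
  if (length(ev) == 0L) {
    return(structure(step_function(numeric(), numeric()), n_events = 0L))
  }
  ut <- sort(unique(ev))
  d <- tabulate(match(ev, ut), length(ut))
  ss <- sort(h$start)
  sp <- sort(h$stop)
  Y <- findInterval(ut, ss, left.open = TRUE) - findInterval(ut, sp, left.open = TRUE)
  stopifnot(all(Y >= d))  # empty risk set at an event time cannot occur
  structure(step_function(ut, cumsum(d / Y)), n_events = length(ev))
}

#' Kaplan-Meier estimator
#'
#' Product-limit estimate of the survival function of a first-event time,
#' computed via [survival::survfit()].
#'
#' @param time Nonnegative event/censoring times.
#' @param status 1 = event, 0 = censored.
#' @return A [step_function()] starting at 1.
#' @export
kaplan_meier <- function(time, status) {
  if (any(time < 0)) stop("times must be nonnegative")
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  step_function(sf$time, sf$surv, v0 = 1)
}

#' Aalen-Johansen estimator of transition probabilities
#'
#' Estimates the matrix of transition probabilities P(s, t) in the
#' illness-death model with recovery as the finite matrix product of
#' `I + increment of the Nelson-Aalen matrix` over the observed transition
#' times in (s, t], with diagonal entries of the hazard-increment matrix
#' equal to minus the off-diagonal row sums. Started from s = 0 this
#' estimates the state occupation probabilities, which remain consistent in
#' non-Markov models under random censoring.
#'
#' @param history An `event_history`.
#' @param s Conditioning (start) time, default 0.
#' @return An object of class `transition_path`: list with `s`, the jump
#'   times `times`, and a `K x 3 x 3` array `P` where `P[k, h+1, j+1]` is
#'   the estimate of P(X_t = j | X_s = h) at the k-th jump time.
#' @export
aalen_johansen <- function(history, s = 0) {
  trans <- list(c(0L, 1L), c(0L, 2L), c(1L, 0L), c(1L, 2L))
  obs <- history$status == 1L & !is.na(history$to)
  ut <- sort(unique(history$stop[obs & history$stop > s]))
  K <- length(ut)
  ## per-transition event counts and per-state risk sets at the pooled times
  dmat <- matrix(0, K, length(trans))
  Ymat <- matrix(0, K, 2L)
  for (hstate in 0:1) {
    h <- history[history$from == hstate, , drop = FALSE]
    Ymat[, hstate + 1L] <- findInterval(ut, sort(h$start), left.open = TRUE) -
      findInterval(ut, sort(h$stop), left.open = TRUE)
  }
  for (j in seq_along(trans)) {
    ev <- history$stop[obs & history$from == trans[[j]][1L] &
                         history$to == trans[[j]][2L]]
    dmat[, j] <- tabulate(match(ev, ut), K)
  }
  P <- array(0, dim = c(K, 3L, 3L))
  cur <- diag(3L)
  for (k in seq_len(K)) {
    A <- diag(3L)
    for (j in seq_along(trans)) {
      if (dmat[k, j] > 0) {
        hh <- trans[[j]][1L] + 1L
        A[hh, trans[[j]][2L] + 1L] <- dmat[k, j] / Ymat[k, hh]
      }
    }
    diag(A) <- diag(A) - (rowSums(A) - 1)
    cur <- cur %*% A
    stopifnot(all(abs(rowSums(cur) - 1) < 1e-10),
              all(cur > -1e-10 & cur < 1 + 1e-10))
    P[k, , ] <- cur
  }
  structure(list(s = s, times = ut, P = P), class = "transition_path")
}

#' @export
print.transition_path <- function(x, ...) {
  cat("Aalen-Johansen transition probabilities from s =", x$s, "with",
      length(x$times), "jumps\n")
  if (length(x$times)) {
    cat("P(s,", max(x$times), ") =\n")
    print(round(x$P[length(x$times), , ], 4))
  }
  invisible(x)
}

#' State occupation probabilities
#'
#' Occupation probabilities Q_l(t) = P(X_t = l), estimated as the
#' state-0 row of the Aalen-Johansen estimator started at s = 0 (all
#' subjects start at home at time 0).
#'
#' @param history An `event_history`.
#' @return Named list of three [step_function()]s (`"0"`, `"1"`, `"2"`).
#' @export
state_occupation <- function(history) {
  aj <- aalen_johansen(history, s = 0)
  out <- lapply(0:2, function(l) {
    step_function(aj$times, aj$P[, 1L, l + 1L], v0 = as.numeric(l == 0L))
  })
  names(out) <- as.character(0:2)
  out
}

#' Average length of stay in hospital up to t
#'
#' The integral over `[0, t]` of the hospital occupation probability
#' Q_1(u): the expected number of days spent in hospital by time t.
#'
#' @param q1 The hospital occupation probability as a [step_function()]
#'   (e.g. `state_occupation(history)[["1"]]`).
#' @param t Time horizon in days (scalar, >= 0).
#' @return Expected hospital days by `t`.
#' @export
average_length_of_stay <- function(q1, t) {
  if (t < 0) stop("`t` must be nonnegative")
  integrate_step(q1, t)
}

#' Marginal mean number of recurrent events
#'
#' Estimates mu(t) = E(number of hospitalizations by t), accounting for
#' death, as the sum over transition times u_k <= t of
#' Q_0(u_k-) * (Nelson-Aalen increment of the home->hospital transition at
#' u_k). The left limit of the occupation probability makes the estimator
#' coincide exactly with the mean observed event count when there is no
#' censoring.
#'
#' @param q0 Occupation probability of the home state as a
#'   [step_function()] (from [state_occupation()]).
#' @param lambda01 Nelson-Aalen estimate of the home->hospital transition
#'   from the same history (from [nelson_aalen()]).
#' @param t Optional time horizon; if supplied the value at `t` is
#'   returned, otherwise the whole path.
#' @return A [step_function()], or a scalar when `t` is given.
#' @export
marginal_mean <- function(q0, lambda01, t = NULL) {
  inc <- step_increments(lambda01)
  if (nrow(inc) && !all(inc$time %in% c(q0$times, 0))) {
    stop("mismatched time supports: `q0` must be estimated on the same history")
  }
  mu <- step_function(inc$time,
                      cumsum(eval_step(q0, inc$time, left = TRUE) * inc$increment))
  if (is.null(t)) mu else eval_step(mu, t)
}

#' Ratio of expected hospitalizations per time alive between arms
#'
#' The between-arm ratio of (expected number of hospitalizations by t)
#' divided by (expected days alive by t), i.e. the marginal mean over the
#' integral of 1 - Q_2. A value below 1 indicates fewer hospitalizations
#' per unit time alive under treatment.
#'
#' @param history An `event_history` containing both arms.
#' @param t Time horizon in days.
#' @param arm Name of the 0/1 treatment column (default `"Z"`).
#' @return An object of class `ratio_summary`: list with the horizon, the
#'   per-arm expected event counts and integrated survival, and the ratio
#'   `rr` (treated / control).
#' @export
rr_ratio <- function(history, t, arm = "Z") {
  per_arm <- lapply(c(0, 1), function(a) {
    h <- history[history[[arm]] == a, , drop = FALSE]
    occ <- state_occupation(h)
    mu <- marginal_mean(occ[["0"]], nelson_aalen(h, 0L, 1L), t)
    alive <- t - integrate_step(occ[["2"]], t)
    list(mu = mu, alive = alive)
  })
  if (any(vapply(per_arm, function(p) p$alive <= 0, TRUE))) {
    stop("integrated survival is zero in one arm")
  }
  rr <- (per_arm[[2]]$mu / per_arm[[2]]$alive) /
    (per_arm[[1]]$mu / per_arm[[1]]$alive)
  structure(list(t = t,
                 mean_events = c(control = per_arm[[1]]$mu,
                                 treated = per_arm[[2]]$mu),
                 days_alive = c(control = per_arm[[1]]$alive,
                                treated = per_arm[[2]]$alive),
                 rr = rr),
            class = "ratio_summary")
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf("RR(%g) = %.4f\n", x$t, x$rr))
  cat(sprintf("  expected events by t:  control %.3f, treated %.3f\n",
              x$mean_events[1], x$mean_events[2]))
  cat(sprintf("  expected days alive:   control %.1f, treated %.1f\n",
              x$days_alive[1], x$days_alive[2]))
  invisible(x)
}

#' Resample subjects (clusters) with replacement
#'
#' @param history An `event_history`.
#' @return An `event_history` of the same size with resampled subjects
#'   relabelled `1..n` (so repeated draws of one subject stay distinct
#'   clusters).
#' @export
resample_subjects <- function(history) {
  ids <- unique(history$id)
  pick <- sample(ids, length(ids), replace = TRUE)
  rows <- split(seq_len(nrow(history)), match(history$id, ids))
  idx <- unlist(rows[match(pick, ids)], use.names = FALSE)
  out <- history[idx, , drop = FALSE]
  out$id <- rep(seq_along(pick), lengths(rows)[match(pick, ids)])
  rownames(out) <- NULL
  new_event_history(out, attr(history, "structure"))
}

#' Basic bootstrap confidence limits
#'
#' Cluster (subject) bootstrap: subjects are resampled with replacement and
#' the statistic recomputed on each resample. The basic bootstrap interval
#' is (2*theta_hat - upper quantile, 2*theta_hat - lower quantile) of the
#' bootstrap distribution.
#'
#' @param history An `event_history`.
#' @param statistic Function taking a history and returning a numeric
#'   vector (e.g. an estimate evaluated on a fixed time grid).
#' @param B Number of bootstrap samples (default 1000).
#' @param level Confidence level (default 0.95).
#' @return List with `estimate`, `lower`, `upper`, and the `B x p` matrix
#'   of bootstrap `replicates`.
#' @export
basic_bootstrap_ci <- function(history, statistic, B = 1000L, level = 0.95) {
  if (B < 2L) stop("`B` must be at least 2")
  est <- statistic(history)
  reps <- matrix(NA_real_, B, length(est))
  for (b in seq_len(B)) reps[b, ] <- statistic(resample_subjects(history))
  alpha <- 1 - level
  qs <- apply(reps, 2L, quantile, probs = c(alpha / 2, 1 - alpha / 2),
              names = FALSE)
  list(estimate = est,
       lower = 2 * est - qs[2L, ],
       upper = 2 * est - qs[1L, ],
       level = level, B = B, replicates = reps)
}
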