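# Shared fixtures and independent oracles for the test suite.

# one subject's records as a data frame row set
rec <- function(id, from, to, start, stop, status = 1L, Z = 0) {
  data.frame(id = id, from = from, to = to, start = start, stop = stop,
             status = status, Z = Z)
}

# the worked illness-death subject: one hospitalization, death at 40
subject_one_stay <- function(id = 1L, Z = 0) {
  rbind(rec(id, 0L, 1L, 0, 10, Z = Z),
        rec(id, 1L, 0L, 10, 15, Z = Z),
        rec(id, 0L, 2L, 15, 40, Z = Z))
}

# death during the second hospital stay
subject_two_stays <- function(id = 1L, Z = 0) {
  from_event_list(id, admissions = c(10, 50), discharges = 15, terminal = 60,
                  died = TRUE, covariates = list(Z = Z))
}

# scenario config with censoring switched off (all subjects followed to death)
config_nocens <- function(id = 1L, n = 100L, alternative = FALSE) {
  cfg <- scenario_config(id, n = n, alternative = alternative)
  cfg$censoring <- "statedep"   # competing-cause mode with rate zero
  cfg$cens_rate <- 0
  cfg
}

# state occupied by a subject at time t (empirical oracle, left-closed from
# transition times: state 2 from the death time onward)
state_at <- function(history, subject, t) {
  r <- history[history$id == subject, , drop = FALSE]
  last <- r[nrow(r), ]
  if (last$status == 1L && last$to == 2L && t >= last$stop) return(2L)
  if (t >= last$stop) return(NA_integer_)   # censored before t
  r$from[r$start <= t & t < r$stop][1L]
}

# brute-force Breslow partial log-likelihood assembled by explicit loops --
# an oracle independent of the cox_fit implementation
brute_pl <- function(beta, start, stop, status, X, strata = NULL) {
  X <- as.matrix(X)
  if (is.null(strata)) strata <- rep(1L, nrow(X))
  eta <- drop(X %*% beta)
  ll <- 0
  for (i in which(status == 1L)) {
    t <- stop[i]
    at_risk <- strata == strata[i] & start < t & stop >= t
    ll <- ll + eta[i] - log(sum(exp(eta[at_risk])))
  }
  ll
}

brute_pl_max <- function(start, stop, status, X, strata = NULL,
                         interval = c(-5, 5)) {
  opt <- optimize(function(b) brute_pl(b, start, stop, status, X, strata),
                  interval = interval, maximum = TRUE, tol = 1e-9)
  opt$maximum
}

# binomial Monte-Carlo acceptance band (central 99.9%)
binom_band <- function(R, p = 0.05) {
  qbinom(c(0.0005, 0.9995), R, p)
}

# rejection count for one covariate from a rejection_summary
pickrej <- function(rs, covariate) {
  as.integer(rs$rejections[rs$covariate == covariate])
}
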