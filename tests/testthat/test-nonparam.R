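test_that("Nelson-Aalen matches the hand-computed worked example", {
  ## events at t=1 (3 at risk) and t=3 (1 at risk; one censored at 2)
  h <- validate_history(rbind(
    rec(1L, 0L, 1L, 0, 1), rec(1L, 1L, NA, 1, 6, status = 0L),
    rec(2L, 0L, NA, 0, 2, status = 0L),
    rec(3L, 0L, 1L, 0, 3), rec(3L, 1L, NA, 3, 6, status = 0L)))
  na01 <- nelson_aalen(h, 0L, 1L)
  expect_equal(eval_step(na01, c(0.5, 1, 2.9, 3, 10)),
               c(0, 1/3, 1/3, 1/3 + 1, 1/3 + 1))
  expect_identical(attr(na01, "n_events"), 2L)
  ## no transitions of the queried type -> zero function
  na12 <- nelson_aalen(h, 1L, 2L)
  expect_equal(eval_step(na12, c(1, 100)), c(0, 0))
})

test_that("Nelson-Aalen is invariant to relabeling and record splitting", {
  h <- simulate_dataset(scenario_config(2, n = 120), rep = 1, seed = 21)
  base <- nelson_aalen(h, 0L, 1L)

  perm <- h
  ids <- unique(h$id)
  newid <- setNames(sample(seq_along(ids)), ids)
  perm$id <- newid[as.character(h$id)]
  relab <- nelson_aalen(perm, 0L, 1L)
  expect_identical(base$times, relab$times)
  expect_identical(base$values, relab$values)

  ## split the longest at-home record at an interior point: risk time unchanged
  split_row <- which.max(ifelse(h$from == 0L, h$stop - h$start, -1))
  mid <- (h$start[split_row] + h$stop[split_row]) / 2
  top <- h[split_row, ]; bottom <- h[split_row, ]
  top$stop <- mid; top$to <- NA_integer_; top$status <- 0L
  bottom$start <- mid
  h_split <- rbind(h[-split_row, ], top, bottom)
  resplit <- nelson_aalen(h_split, 0L, 1L)
  expect_equal(base$times, resplit$times)
  expect_equal(base$values, resplit$values)
})

test_that("Kaplan-Meier reproduces the product-limit hand example", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(eval_step(km, c(0.5, 1, 2.5, 3, 9)), c(1, 2/3, 2/3, 0, 0))
  flat <- kaplan_meier(c(5, 7), c(0, 0))
  expect_equal(eval_step(flat, c(1, 10)), c(1, 1))
})

test_that("Aalen-Johansen occupation equals empirical fractions without censoring", {
  h <- simulate_dataset(config_nocens(2, n = 150), rep = 1, seed = 61)
  occ <- state_occupation(h)
  ids <- unique(h$id)
  for (t in c(100, 750, 2200)) {
    emp <- table(factor(vapply(ids, function(s) state_at(h, s, t), 1L),
                        levels = 0:2)) / length(ids)
    for (l in 0:2) {
      expect_equal(eval_step(occ[[as.character(l)]], t), unname(emp[l + 1]),
                   tolerance = 1e-12)
    }
  }
})

test_that("transition-probability paths are stochastic matrices; P(s,s) = I", {
  h <- simulate_dataset(scenario_config(3, n = 100), rep = 1, seed = 71)
  aj <- aalen_johansen(h, s = 200)
  expect_true(all(aj$times > 200))
  K <- length(aj$times)
  expect_equal(apply(aj$P, 1, rowSums), matrix(1, 3, K), tolerance = 1e-10)
  expect_true(all(aj$P >= -1e-12 & aj$P <= 1 + 1e-12))
  empty <- aalen_johansen(h, s = max(h$stop))
  expect_identical(length(empty$times), 0L)
})

test_that("with no recovery the AJ state-1 entry equals the cumulative incidence", {
  ## competing-risks layout: a single transition out of home, absorbing stays
  set.seed(81)
  n <- 60
  t1 <- rexp(n, 0.01)
  cause <- sample(c(1L, 2L, 0L), n, replace = TRUE, prob = c(.5, .3, .2))
  recs <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (cause[i] == 0L) return(rec(i, 0L, NA, 0, t1[i], status = 0L))
    first <- rec(i, 0L, cause[i], 0, t1[i])
    if (cause[i] == 1L) rbind(first, rec(i, 1L, NA, t1[i], t1[i] + 5, status = 0L))
    else first
  }))
  h <- validate_history(recs)
  aj <- aalen_johansen(h, s = 0)
  ## independent formula: CIF_1(t) = sum S(u-) dLambda_01(u)
  exit <- t1                       # time of leaving the initial state
  exit_status <- as.integer(cause != 0L)
  S <- kaplan_meier(exit, exit_status)
  L01 <- nelson_aalen(h, 0L, 1L)
  inc <- step_increments(L01)
  cif <- step_function(inc$time,
                       cumsum(eval_step(S, inc$time, left = TRUE) * inc$increment))
  ## but the AJ path jumps at hospitalization times only for entry 0->1
  for (t in c(20, 80, 200, 400)) {
    p01 <- eval_step(step_function(aj$times, aj$P[, 1, 2],
                                   v0 = 0), t)
    expect_equal(p01, eval_step(cif, t), tolerance = 1e-12)
  }
})

test_that("marginal mean and length of stay reduce to sample means without censoring", {
  h <- simulate_dataset(config_nocens(1, n = 120), rep = 1, seed = 91)
  occ <- state_occupation(h)
  mu <- marginal_mean(occ[["0"]], nelson_aalen(h, 0L, 1L))
  ids <- unique(h$id)
  for (t in c(300, 1000, 4000)) {
    mean_count <- mean(vapply(ids, function(s) n_recurrent(h, s, t), 1L))
    expect_equal(eval_step(mu, t), mean_count, tolerance = 1e-12)
    hosp_days <- mean(vapply(ids, function(s) {
      r <- h[h$id == s & h$from == 1L, , drop = FALSE]
      sum(pmax(0, pmin(r$stop, t) - pmin(r$start, t)))
    }, 1))
    expect_equal(average_length_of_stay(occ[["1"]], t), hosp_days,
                 tolerance = 1e-12)
  }
})

test_that("a lone subject with one admission has marginal mean one", {
  h <- validate_history(rbind(rec(1L, 0L, 1L, 0, 5), rec(1L, 1L, 2L, 5, 8)))
  occ <- state_occupation(h)
  mu <- marginal_mean(occ[["0"]], nelson_aalen(h, 0L, 1L))
  expect_equal(eval_step(mu, 1e9), 1)
  expect_error(marginal_mean(step_function(c(99), c(0.5), v0 = 1),
                             nelson_aalen(h, 0L, 1L)), "mismatched")
})

test_that("the hospitalization-per-time-alive ratio is 1 for mirrored arms", {
  one_arm <- simulate_dataset(config_nocens(1, n = 40), rep = 1, seed = 101)
  mirrored <- as.data.frame(one_arm)
  mirrored$Z <- 0
  other <- mirrored
  other$id <- other$id + 1000L
  other$Z <- 1
  h <- validate_history(rbind(mirrored, other))
  rs <- rr_ratio(h, 1500)
  expect_equal(rs$rr, 1.0, tolerance = 1e-12)
  expect_equal(unname(rs$mean_events[1]), unname(rs$mean_events[2]))
})

test_that("occupation probabilities track the constant-rate Markov solution", {
  ## closed-form oracle: matrix exponential of the generator
  Q <- matrix(c(-0.0027, 0.002, 0.0007,
                0.004, -0.00475, 0.00075,
                0, 0, 0), 3, 3, byrow = TRUE)
  h <- simulate_dataset(config_nocens(1, n = 2500), rep = 1, seed = 111)
  occ <- state_occupation(h)
  for (t in c(500, 1500)) {
    Pt <- as.matrix(Matrix::expm(Q * t))
    for (l in 0:2) {
      p <- Pt[1, l + 1]
      mc_se <- sqrt(p * (1 - p) / 2500)
      expect_lt(abs(eval_step(occ[[as.character(l)]], t) - p), 3.5 * mc_se)
    }
  }
})

test_that("basic bootstrap limits are the reflected quantiles", {
  h <- simulate_dataset(scenario_config(1, n = 60), rep = 1, seed = 121)
  const <- basic_bootstrap_ci(h, function(x) 42, B = 10)
  expect_equal(const$lower, 42)
  expect_equal(const$upper, 42)
  expect_error(basic_bootstrap_ci(h, function(x) 1, B = 1), "at least 2")

  set.seed(5)
  stat <- function(x) eval_step(marginal_mean(state_occupation(x)[["0"]],
                                              nelson_aalen(x, 0L, 1L)), 800)
  ci <- basic_bootstrap_ci(h, stat, B = 40)
  qs <- quantile(ci$replicates[, 1], c(0.025, 0.975), names = FALSE)
  expect_equal(ci$lower, 2 * ci$estimate - qs[2])
  expect_equal(ci$upper, 2 * ci$estimate - qs[1])
  expect_lte(ci$lower, ci$upper)
})
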