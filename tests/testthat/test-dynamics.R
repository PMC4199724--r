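test_that("search_params validates its domain", {
  expect_error(search_params(N = 0), "N must be")
  expect_error(search_params(N = 5, p = 1.2), "p must be")
  expect_error(search_params(N = 5, p = 0.5, K = 5), "K must satisfy")
  expect_error(search_params(N = 1, p = 0.5, K = 0), "K must satisfy|requires")
  expect_error(search_params(N = 5, p = 0.5, K = 0), "requires")
  expect_s3_class(search_params(N = 1, p = 0, K = 0), "search_params")
})

test_that("update_agent implements the move/imitate/waste rules", {
  pz <- small4()
  set.seed(10)
  net <- build_network(4, 3)
  st <- init_population(pz, 4)

  # p = 0: always a move
  prm0 <- search_params(N = 4, p = 0, K = 3, seed = 1)
  out <- replicate(20, update_agent(1, pz, net, st, prm0)$outcome)
  expect_true(all(out == "moved"))

  # p = 1, target strictly cheaper than every influencer: wasted, unchanged
  prm1 <- search_params(N = 4, p = 1, K = 3, seed = 1)
  st$costs <- c(0, 50, 60, 70)
  res <- update_agent(1, pz, net, st, prm1)
  expect_equal(res$outcome, "wasted")
  expect_identical(res$state$assignments, st$assignments)

  # p = 1, target identical to its model: wasted
  st2 <- st
  for (i in 2:4) st2$assignments[[i]] <- st2$assignments[[1]]
  st2$costs <- rep(cost(pz, st2$assignments[[1]]), 4)
  res2 <- update_agent(1, pz, net, st2, prm1)
  expect_equal(res2$outcome, "wasted")

  # p = 1, equal costs but different strings: the copy proceeds
  set.seed(77)
  st3 <- init_population(pz, 4)
  st3$costs <- rep(5, 4)
  res3 <- update_agent(1, pz, net, st3, prm1)
  expect_equal(res3$outcome, "imitated")
})

test_that("run_trial updates every agent once in a random order", {
  pz <- small4()
  set.seed(20)
  net <- build_network(5, 2)
  st <- init_population(pz, 5)
  prm <- search_params(N = 5, p = 0.3, K = 2, seed = 20)
  st2 <- run_trial(pz, net, st, prm)
  expect_length(attr(st2, "outcomes"), 5L)
  expect_equal(st2$trial_index, 1L)

  # with p = 0 a trial is N independent elementary moves: every agent's
  # state is one transposition away from its previous state
  prm0 <- search_params(N = 5, p = 0, K = 2, seed = 20)
  st3 <- run_trial(pz, net, st, prm0)
  for (i in 1:5)
    expect_lte(sum(st3$assignments[[i]] != st$assignments[[i]]), 2L)
})

test_that("compiled and reference engines produce identical trajectories", {
  pz <- small4()
  for (sd in c(2, 7, 13)) {
    prm <- search_params(N = 6, p = 0.4, K = 3, seed = sd,
                         max_trials = 2000)
    r1 <- run_search(pz, prm, engine = "cpp", record_trace = TRUE)
    r2 <- run_search(pz, prm, engine = "r", record_trace = TRUE)
    expect_equal(r1$t_star, r2$t_star)
    expect_equal(r1$wasted_updates, r2$wasted_updates)
    expect_equal(r1$n_imitated, r2$n_imitated)
    expect_equal(r1$n_change_events, r2$n_change_events)
    expect_equal(r1$capped, r2$capped)
    expect_equal(r1$min_trace, r2$min_trace)
  }
  # and with the global move
  prm <- search_params(N = 4, p = 0, K = 0, seed = 3, max_trials = 2000,
                       move_kind = "global")
  r1 <- run_search(pz, prm, engine = "cpp", record_trace = TRUE)
  r2 <- run_search(pz, prm, engine = "r", record_trace = TRUE)
  expect_equal(r1$min_trace, r2$min_trace)
  expect_equal(r1$t_star, r2$t_star)
})

test_that("run_search is deterministic and conserves update counts", {
  pz <- small4()
  prm <- search_params(N = 5, p = 0.5, K = 4, seed = 101)
  r1 <- run_search(pz, prm)
  r2 <- run_search(pz, prm)
  r1$min_trace <- r2$min_trace <- NULL
  expect_identical(r1, r2)

  expect_equal(r1$total_cost, prm$N * r1$t_star)
  expect_equal(r1$rescaled_cost, r1$total_cost / pz$space_size)
  expect_equal(r1$n_imitated + r1$n_moved + r1$wasted_updates,
               prm$N * r1$t_star)
  expect_gte(r1$stasis_M, 1)
})

test_that("trace bookkeeping matches stasis_statistic, and minima can rise", {
  # worked example of the counting rule
  s <- stasis_statistic(c(5, 5, 5, 3, 3, 9, 9, 9, 9), t_star = 9)
  expect_equal(s$n_change_events, 2L)
  expect_equal(s$stasis_M, 4.5)
  expect_equal(stasis_statistic(c(7, 7, 7))$n_change_events, 0L)
  expect_equal(stasis_statistic(c(7, 7, 7))$stasis_M, 2L)

  pz <- small4()
  rose <- FALSE
  for (sd in 1:10) {
    r <- run_search(pz, search_params(N = 4, p = 0, K = 0, seed = sd),
                    record_trace = TRUE)
    s <- stasis_statistic(r$min_trace)
    expect_equal(s$n_change_events, r$n_change_events)
    expect_equal(s$stasis_M, r$stasis_M)
    if (any(diff(r$min_trace) > 0)) rose <- TRUE
  }
  expect_true(rose)  # no elitism: the population minimum can increase
})

test_that("an initial population containing the solution halts after trial 1", {
  # the check happens at trial end only, so t* counts one full trial even
  # when trial 0 already holds a solution; with p = 1 the solution holder's
  # update is wasted (it is strictly cheaper than any model), so the
  # solution survives the trial deterministically
  pz <- parse_puzzle("A+A=B")  # 4 of 90 states are solutions
  seed_hit <- NA
  for (sd in 1:60) {
    set.seed(sd)
    # replay the engine's draw order: network first, then the population
    invisible(build_network(25, 24))
    st <- init_population(pz, 25)
    if (sum(st$costs == 0) == 1) { seed_hit <- sd; break }
  }
  expect_false(is.na(seed_hit))
  r <- run_search(pz, search_params(N = 25, p = 1, K = 24, seed = seed_hit,
                                    max_trials = 50))
  expect_equal(r$t_star, 1)
  expect_equal(r$total_cost, 25)
  expect_equal(r$rescaled_cost, 25 / pz$space_size)
})

test_that("max_trials caps the run and is reported, not raised", {
  pz <- donald()
  r <- run_search(pz, search_params(N = 5, p = 0, K = 0, seed = 1,
                                    max_trials = 10))
  expect_true(r$capped)
  expect_equal(r$t_star, 10)
})

test_that("global-move first-passage times follow the closed-form geometric law", {
  pz <- small4()
  expect_equal(count_solutions(pz), 1)  # prerequisite of the closed form
  N <- 5
  q <- 1 / pz$space_size
  res <- run_many(pz, N = N, p = 0, K = 0, reps = 150, base_seed = 500,
                  move_kind = "global")
  ts <- vapply(res, function(r) r$t_star, numeric(1))
  # P(t* > t) = (1-q)^(N t): compare empirical and theoretical CDFs
  grid <- stats::quantile(ts, probs = seq(0.05, 0.95, by = 0.05))
  Femp <- stats::ecdf(ts)(grid)
  Fth <- 1 - (1 - q)^(N * grid)
  expect_lt(max(abs(Femp - Fth)), 1.36 / sqrt(150) + 0.02)
})
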