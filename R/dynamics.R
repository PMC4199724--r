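#' Search parameters
#'
#' Bundles the model parameters of a single search: the number of agents
#' `N`, the imitation probability `p`, the influence-network size `K`, the
#' RNG seed, and the trial cap.
#'
#' @param N number of agents (>= 1).
#' @param p imitation probability in `[0, 1]`; `p = 0` is the independent
#'   search.  `p = 1` makes the cost diverge in the fully connected system
#'   (the elementary move is never taken) and is allowed only under the
#'   `max_trials` cap.
#' @param K influencers per agent; `p > 0` requires `K >= 1` and `N >= 2`.
#'   `K = N - 1` is the fully connected system.
#' @param seed integer seed; a single RNG stream derived from it drives
#'   network construction, initialisation, update order, move choices and
#'   tie-breaks, in that documented order, so the seed fully determines the
#'   run.
#' @param max_trials trial cap; `NULL` means `ceiling(100 * |S| / N)` where
#'   `|S|` is the state-space size — far beyond the exponential scale of
#'   typical searches, so it only bounds pathological settings (p near 1).
#' @param move_kind `"elementary"` (local transposition) or `"global"`
#'   (redraw the whole assignment each update; baseline variant).
#' @return an object of class `search_params`.
#' @export
search_params <- function(N, p = 0, K = max(N - 1L, 0L), seed = 1L,
                          max_trials = NULL,
                          move_kind = c("elementary", "global")) {
  move_kind <- match.arg(move_kind)
  N <- as.integer(N); K <- as.integer(K)
  if (N < 1L) stop("N must be >= 1")
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  if (K < 0L || K > N - 1L) stop("K must satisfy 0 <= K <= N - 1")
  if (p > 0 && (K < 1L || N < 2L))
    stop("p > 0 requires K >= 1 and N >= 2")
  if (!is.null(max_trials)) {
    max_trials <- as.numeric(max_trials)
    if (max_trials < 1) stop("max_trials must be >= 1")
  }
  structure(list(N = N, p = p, K = K, seed = as.integer(seed),
                 max_trials = max_trials, move_kind = move_kind),
            class = "search_params")
}

#' Update one agent (asynchronous step)
#'
#' With probability `p` the agent attempts to imitate: its model string is
#' selected among its influencers; if the agent's cost is strictly lower
#' than the model's, or the agent is identical to the model, the update
#' opportunity is wasted and the state is unchanged; otherwise one
#' differing assignment is assimilated via [imitate()].  With probability
#' `1 - p` the agent performs the move prescribed by `move_kind`.  Cached
#' costs are updated in place.
#'
#' @param agent index of the agent to update.
#' @param pz a [parse_puzzle()] object.
#' @param net an [build_network()] object.
#' @param state a [init_population()] object.
#' @param params a [search_params()] object.
#' @return list with the updated `state` and `outcome`, one of `"moved"`,
#'   `"imitated"`, `"wasted"`.
#' @export
update_agent <- function(agent, pz, net, state, params) {
  u <- runif(1L)
  if (u < params$p) {
    sm <- select_model(agent, net, state)
    if (state$costs[agent] < sm$cost) {
      outcome <- "wasted"
    } else {
      tgt <- state$assignments[[agent]]
      mod <- state$assignments[[sm$index]]
      if (all(tgt[seq_len(pz$L)] == mod[seq_len(pz$L)])) {
        outcome <- "wasted"
      } else {
        a2 <- imitate(tgt, mod, pz)
        state$assignments[[agent]] <- a2
        state$costs[agent] <- cost(pz, a2)
        outcome <- "imitated"
      }
    }
  } else {
    a2 <- if (params$move_kind == "global") global_move(pz)
          else elementary_move(state$assignments[[agent]])
    state$assignments[[agent]] <- a2
    state$costs[agent] <- cost(pz, a2)
    outcome <- "moved"
  }
  list(state = state, outcome = outcome)
}

#' Run one trial (all agents updated once, in random order)
#'
#' A trial draws a uniformly random update order of the `N` agents and
#' applies [update_agent()] to each in turn.  The process is asynchronous:
#' model selections later in the trial see all updates already applied
#' within it.  The trial index is incremented at the end.
#'
#' @inheritParams update_agent
#' @return the updated `population_state`, with an attribute `outcomes`
#'   (character vector of per-agent outcomes in update order).
#' @export
run_trial <- function(pz, net, state, params) {
  N <- params$N
  ord <- .ps_shuffle(seq_len(N))
  outcomes <- character(N)
  for (k in seq_len(N)) {
    res <- update_agent(ord[k], pz, net, state, params)
    state <- res$state
    outcomes[k] <- res$outcome
  }
  state$trial_index <- state$trial_index + 1L
  attr(state, "outcomes") <- outcomes
  state
}

#' Run a complete search
#'
#' Initialises the influence network and the population from the seed, then
#' repeats trials until some agent has cost zero at a trial-end check (a
#' solution found mid-trial still completes the trial, so the computational
#' cost is exactly `N * t_star` agent updates).  Along the way the
#' population's minimal cost is recorded per trial; a change event is any
#' difference (up or down) between consecutive trials' minima, and the
#' stasis statistic `M = t_star / n_change_events` is the mean number of
#' trials the leading cost persists.
#'
#' Two engines produce byte-identical results for a given seed: the
#' compiled engine (`"cpp"`, default; used for production runs) and a pure
#' R reference built from the exported operators (`"r"`; tractable only for
#' small state spaces).  The test suite checks their trajectory-level
#' agreement.
#'
#' @inheritParams update_agent
#' @param engine `"cpp"` or `"r"`.
#' @param record_trace keep the per-trial minimal-cost series (memory grows
#'   with `t_star`; intended for diagnostics and small runs).
#' @return an object of class `search_result`: list with `t_star` (trials
#'   to success), `total_cost` (`N * t_star`), `rescaled_cost`
#'   (`total_cost / pz$space_size`), `n_change_events`, `stasis_M`,
#'   `wasted_updates`, `n_imitated`, `n_moved`, `capped` (TRUE if
#'   `max_trials` was reached without a solution), `seed`, `params`,
#'   `engine`, and `min_trace` (NULL unless `record_trace`).
#' @examples
#' pz <- parse_puzzle("DONALD+GERALD=ROBERT")
#' res <- run_search(pz, search_params(N = 10, p = 0.5, K = 9, seed = 42))
#' res$rescaled_cost
#' @export
run_search <- function(pz, params, engine = c("cpp", "r"),
                       record_trace = FALSE) {
  engine <- match.arg(engine)
  stopifnot(inherits(pz, "puzzle"), inherits(params, "search_params"))
  max_trials <- params$max_trials
  if (is.null(max_trials))
    max_trials <- ceiling(100 * pz$space_size / params$N)
  set.seed(params$seed)

  if (engine == "cpp") {
    raw <- cpp_run_search(pz$coef, pz$leading_idx - 1L, pz$penalty_cost,
                          pz$L, params$N, params$p, params$K,
                          as.integer(params$move_kind == "global"),
                          as.numeric(max_trials), as.integer(record_trace))
  } else {
    net <- build_network(params$N, params$K)
    state <- init_population(pz, params$N)
    prev <- min(state$costs)
    trace <- if (record_trace) prev else NULL
    events <- 0; wasted <- 0; n_imit <- 0; n_move <- 0
    t <- 0; capped <- FALSE
    repeat {
      t <- t + 1
      state <- run_trial(pz, net, state, params)
      out <- attr(state, "outcomes")
      wasted <- wasted + sum(out == "wasted")
      n_imit <- n_imit + sum(out == "imitated")
      n_move <- n_move + sum(out == "moved")
      mn <- min(state$costs)
      if (record_trace) trace <- c(trace, mn)
      if (mn != prev) events <- events + 1
      prev <- mn
      if (mn == 0) break
      if (t >= max_trials) { capped <- TRUE; break }
    }
    raw <- list(t_star = t, capped = capped, wasted_updates = wasted,
                n_change_events = events, n_imitated = n_imit,
                n_moved = n_move)
    if (record_trace) raw$min_trace <- trace
  }

  t_star <- raw$t_star
  events <- raw$n_change_events
  structure(list(
    t_star = t_star,
    total_cost = params$N * t_star,
    rescaled_cost = params$N * t_star / pz$space_size,
    n_change_events = events,
    stasis_M = if (events == 0) t_star else t_star / events,
    wasted_updates = raw$wasted_updates,
    n_imitated = raw$n_imitated,
    n_moved = raw$n_moved,
    capped = isTRUE(raw$capped),
    seed = params$seed,
    params = params,
    engine = engine,
    min_trace = raw$min_trace
  ), class = "search_result")
}

#' Change events and stasis statistic of a minimal-cost trace
#'
#' Given the per-trial series of the population's minimal cost, counts the
#' change events (any difference, greater or less, between consecutive
#' entries) and returns the stasis statistic `M = t_star / n_change_events`
#' (the mean number of trials between consecutive change events, i.e. the
#' mean stasis duration); when no change event occurs `M = t_star`.
#' [run_search()] applies the same counting rule online, starting from the
#' trial-0 (initial population) minimum.
#'
#' @param min_costs numeric vector of per-trial minimal costs.
#' @param t_star number of trials the series spans; defaults to
#'   `length(min_costs) - 1`, the correct value for a [run_search()] trace
#'   (which includes the trial-0 entry).
#' @return list with `n_change_events` and `stasis_M`.
#' @examples
#' stasis_statistic(c(5, 5, 5, 3, 3, 9, 9, 9, 9), t_star = 9)
#' @export
stasis_statistic <- function(min_costs, t_star = length(min_costs) - 1L) {
  ev <- sum(diff(min_costs) != 0)
  list(n_change_events = ev,
       stasis_M = if (ev == 0) t_star else t_star / ev)
}

#' @export
print.search_result <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "search_result: N=%d p=%g K=%d %s seed=%d%s\n", p$N, p$p, p$K,
    p$move_kind, x$seed, if (x$capped) " [CAPPED]" else ""))
  cat(sprintf(
    "  t*=%g  cost=N*t*=%g  rescaled=%.4g  change events=%g  M=%.3g  wasted=%g\n",
    x$t_star, x$total_cost, x$rescaled_cost, x$n_change_events, x$stasis_M,
    x$wasted_updates))
  invisible(x)
}
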