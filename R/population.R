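#' Build fixed influence networks
#'
#' Each agent is assigned `K` distinct influencers sampled uniformly without
#' replacement from the other `N - 1` agents.  Links are unidirectional and
#' the network is kept fixed for the entire search.  `K = N - 1` gives the
#' fully connected system, in which every agent's model is the lowest-cost
#' string among all other agents.
#'
#' @param N number of agents.
#' @param K influencers per agent, `0 <= K <= N - 1` (`K = 0` only makes
#'   sense with imitation probability `p = 0`).
#' @return an object of class `influence_network`: a list of `N` integer
#'   vectors of length `K` (agent indices, 1-based), with attributes `N`
#'   and `K`.
#' @examples
#' set.seed(1)
#' net <- build_network(10, 3)
#' lengths(net)
#' @export
build_network <- function(N, K) {
  N <- as.integer(N); K <- as.integer(K)
  if (N < 1L) stop("N must be >= 1")
  if (K < 0L || K > N - 1L)
    stop("K must satisfy 0 <= K <= N - 1 (got K = ", K, ", N = ", N, ")")
  net <- vector("list", N)
  for (i in seq_len(N)) {
    others <- seq_len(N)[-i]
    net[[i]] <- if (K > 0L) .ps_sample_k(others, K) else integer(0L)
  }
  structure(net, N = N, K = K, class = "influence_network")
}

#' Initialise a population of agents
#'
#' Associates an independent uniformly random assignment with each agent and
#' caches its cost.  The cached costs are kept coherent with the assignments
#' by every update operation; [run_trial()] and the compiled engine rely on
#' this cache when selecting model strings.
#'
#' @param pz a [parse_puzzle()] object.
#' @param N number of agents.
#' @return an object of class `population_state`: list with `assignments`
#'   (list of N assignments), `costs` (numeric N) and `trial_index`
#'   (starts at 0; the initial draw is trial 0 and is not counted in
#'   `t_star`).
#' @export
init_population <- function(pz, N) {
  N <- as.integer(N)
  assignments <- vector("list", N)
  costs <- numeric(N)
  for (i in seq_len(N)) {
    assignments[[i]] <- random_assignment(pz)
    costs[i] <- cost(pz, assignments[[i]])
  }
  structure(list(assignments = assignments, costs = costs,
                 trial_index = 0L),
            class = "population_state")
}

#' Select an agent's model string
#'
#' The model is the influencer with the lowest cached cost; ties are broken
#' uniformly at random (a fixed-index rule would bias leadership-stasis
#' statistics).  Because costs are read from the live cache, the selection
#' reflects all updates already applied earlier in the current trial.
#'
#' @param agent index of the target agent.
#' @param net an [build_network()] object.
#' @param state a [init_population()] object.
#' @return list with `index` (the model agent) and `cost` (its cached
#'   cost).
#' @export
select_model <- function(agent, net, state) {
  infl <- net[[agent]]
  if (length(infl) == 0L)
    stop("agent ", agent, " has an empty influencer list")
  cc <- state$costs[infl]
  best <- min(cc)
  ties <- infl[cc == best]
  idx <- if (length(ties) > 1L) ties[.ps_randint(length(ties)) + 1L]
         else ties[1L]
  list(index = idx, cost = best)
}

#' Write / read an influence network as an edge list
#'
#' Plain-text dump (`agent_id influencer_id` per line) for reproducibility
#' audits.
#'
#' @param net an `influence_network`.
#' @param file path.
#' @return `write_network` returns `file` invisibly; `read_network` returns
#'   an `influence_network`.
#' @export
write_network <- function(net, file) {
  edges <- do.call(rbind, lapply(seq_along(net), function(i) {
    if (length(net[[i]]) == 0L) return(NULL)
    cbind(i, net[[i]])
  }))
  utils::write.table(edges, file, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_network
#' @param N number of agents (needed because isolated agents leave no
#'   edges).
#' @export
read_network <- function(file, N) {
  edges <- utils::read.table(file, col.names = c("agent", "influencer"))
  net <- lapply(seq_len(N), function(i)
    as.integer(edges$influencer[edges$agent == i]))
  K <- length(net[[1L]])
  structure(net, N = as.integer(N), K = K, class = "influence_network")
}
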