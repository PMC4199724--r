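# Fixtures are built in code, never stored.

donald <- function() parse_puzzle("DONALD+GERALD=ROBERT")

# the unique solution of DONALD+GERALD=ROBERT, alphabet order DONALGERBT
donald_solution <- function(pz = donald())
  as_assignment(pz, c(5L, 2L, 6L, 4L, 8L, 1L, 9L, 7L, 3L, 0L))

# a 4-letter puzzle with a unique solution (A=1, C=5, B=3, D=8; verified by
# enumeration in test-puzzle.R); state space 10*9*8*7 = 5040
small4 <- function() parse_puzzle("ACB+ADC=BBD")

# 3-letter puzzle used for ergodicity / uniformity checks (many solutions)
small3 <- function() parse_puzzle("AB+CB=CA")

run_many <- function(pz, N, p, K, reps, base_seed,
                     move_kind = "elementary", max_trials = NULL) {
  lapply(seq_len(reps), function(i)
    run_search(pz, search_params(N = N, p = p, K = K, seed = base_seed + i,
                                 max_trials = max_trials,
                                 move_kind = move_kind)))
}

mean_rescaled <- function(results)
  mean(vapply(results, function(r) r$rescaled_cost, numeric(1)))

# independent oracle for solution counting on small alphabets: enumerate
# injective digit tuples with plain R arithmetic on the words themselves
# (no use of the package's coefficient machinery)
oracle_count_solutions <- function(expr) {
  parts <- strsplit(expr, "[+=]")[[1]]
  letters_all <- unique(strsplit(gsub("[+=]", "", expr), "")[[1]])
  L <- length(letters_all)
  stopifnot(L <= 4)
  leading <- unique(substr(parts, 1, 1))
  val <- function(word, digs) {
    ch <- strsplit(word, "")[[1]]
    sum(digs[match(ch, letters_all)] * 10^(length(ch) - seq_along(ch)))
  }
  tuples <- expand.grid(rep(list(0:9), L))
  ok <- apply(tuples, 1, function(d) length(unique(d)) == L)
  tuples <- tuples[ok, , drop = FALSE]
  n <- 0
  for (r in seq_len(nrow(tuples))) {
    digs <- as.numeric(tuples[r, ])
    if (any(digs[match(leading, letters_all)] == 0)) next
    if (val(parts[3], digs) == val(parts[1], digs) + val(parts[2], digs))
      n <- n + 1
  }
  n
}
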