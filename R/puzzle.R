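#' Parse a cryptarithmetic puzzle
#'
#' A cryptarithmetic (alphametic) puzzle is a sum `WORD+WORD=WORD` in which
#' every letter stands for a distinct decimal digit and the leading letter of
#' each word may not be assigned digit 0.  The classic ten-letter instance is
#' `DONALD+GERALD=ROBERT`, whose unique solution assigns
#' D=5, O=2, N=6, A=4, L=8, G=1, E=9, R=7, B=3, T=0.
#'
#' The parsed object records the alphabet in first-occurrence order (scanning
#' operand 1, then operand 2, then the result), the set of leading letters,
#' and a vector of net place-value coefficients `coef` such that the signed
#' discrepancy of an assignment `d` is `sum(coef * d)`; the cost of an
#' assignment is the absolute value of that discrepancy, or `penalty_cost`
#' for assignments that put a 0 on a leading letter.
#'
#' @param text a single string of the form `"WORD+WORD=WORD"`, uppercase
#'   A-Z; surrounding whitespace is ignored.
#' @param penalty_cost cost charged to invalid (leading-zero) assignments.
#'   Must strictly exceed the largest attainable valid cost so that invalid
#'   strings can never outrank valid ones; the default 1e7 covers words of
#'   up to 7 letters.
#' @return an object of class `puzzle`: a list with elements `operand1`,
#'   `operand2`, `result`, `alphabet`, `leading_letters`, `leading_idx`,
#'   `coef` (length 10, zero-padded beyond the alphabet), `L` (alphabet
#'   size), `space_size` (number of injective letter-to-digit maps,
#'   `10!/(10-L)!`) and `penalty_cost`.
#' @examples
#' pz <- parse_puzzle("DONALD+GERALD=ROBERT")
#' pz$alphabet
#' pz$space_size  # 10! = 3,628,800
#' @export
parse_puzzle <- function(text, penalty_cost = 1e7) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("[[:space:]]", "", text)
  if (!grepl("^[A-Z]+\\+[A-Z]+=[A-Z]+$", text))
    stop("malformed puzzle expression; expected WORD+WORD=WORD in uppercase")
  parts <- strsplit(text, "[+=]")[[1L]]
  operand1 <- parts[1L]; operand2 <- parts[2L]; result <- parts[3L]

  letters_seq <- strsplit(paste0(operand1, operand2, result), "")[[1L]]
  alphabet <- unique(letters_seq)
  L <- length(alphabet)
  if (L > 10L)
    stop("more than 10 distinct letters (", L, "); no injective digit map exists")
  if (L < 2L)
    stop("puzzle must use at least 2 distinct letters")

  leading_letters <- unique(substr(c(operand1, operand2, result), 1L, 1L))
  leading_idx <- match(leading_letters, alphabet)

  # net place-value coefficients: + for the result, - for the operands
  coef <- numeric(10L)
  add_word <- function(coef, word, sign) {
    ch <- strsplit(word, "")[[1L]]
    n <- length(ch)
    idx <- match(ch, alphabet)
    for (k in seq_len(n))  # loop: letters repeat within a word
      coef[idx[k]] <- coef[idx[k]] + sign * 10^(n - k)
    coef
  }
  coef <- add_word(coef, result, +1)
  coef <- add_word(coef, operand1, -1)
  coef <- add_word(coef, operand2, -1)

  # largest attainable valid cost: |R - O1 - O2| is bounded by the larger of
  # the maximal result value and the maximal operand sum
  bound <- max(10^nchar(result) - 1,
               (10^nchar(operand1) - 1) + (10^nchar(operand2) - 1))
  if (penalty_cost <= bound)
    stop("penalty_cost (", penalty_cost,
         ") must exceed the maximum attainable valid cost (", bound, ")")

  structure(
    list(operand1 = operand1, operand2 = operand2, result = result,
         alphabet = alphabet, leading_letters = leading_letters,
         leading_idx = leading_idx, coef = coef, L = L,
         space_size = prod(seq(10L, by = -1L, length.out = L)),
         penalty_cost = penalty_cost),
    class = "puzzle")
}

#' @export
print.puzzle <- function(x, ...) {
  cat(sprintf("%s+%s=%s\n", x$operand1, x$operand2, x$result))
  cat(sprintf("  %d letters (%s), %s states, penalty %g\n", x$L,
              paste(x$alphabet, collapse = ""),
              format(x$space_size, big.mark = ","), x$penalty_cost))
  invisible(x)
}

#' Build an assignment from visible digits
#'
#' Agent states are stored as a full permutation of the digits 0-9: slot `i`
#' (for `i <= L`) holds the digit assigned to the `i`-th letter of the
#' puzzle alphabet, and slots `L+1..10` hold the unused digits.  Keeping the
#' unused digits as hidden slots makes the elementary transposition move
#' ergodic over all injective maps even when the puzzle has fewer than 10
#' letters (a swap with a hidden slot substitutes an unused digit).
#'
#' @param pz a [parse_puzzle()] object.
#' @param digits integer vector of length `pz$L`: distinct digits in 0..9,
#'   in alphabet order.  Unused digits fill the hidden slots in ascending
#'   order.
#' @return an integer vector of length 10 (the internal assignment form).
#' @examples
#' pz <- parse_puzzle("DONALD+GERALD=ROBERT")
#' sol <- as_assignment(pz, c(5, 2, 6, 4, 8, 1, 9, 7, 3, 0))
#' is_solution(pz, sol)
#' @export
as_assignment <- function(pz, digits) {
  digits <- as.integer(digits)
  if (length(digits) != pz$L || anyDuplicated(digits) ||
      any(digits < 0L | digits > 9L))
    stop("digits must be ", pz$L, " distinct integers in 0..9")
  c(digits, setdiff(0:9, digits))
}

#' Uniform random assignment
#'
#' Draws a uniformly random injective letter-to-digit map (as a full 10-slot
#' permutation) using the package's Fisher-Yates protocol, so results are
#' reproducible under [set.seed()].
#'
#' @inheritParams as_assignment
#' @return an integer vector of length 10.
#' @export
random_assignment <- function(pz) {
  .ps_shuffle(0:9)
}

#' Visible digits of an assignment
#'
#' @inheritParams as_assignment
#' @param a an assignment (length-10 integer vector).
#' @return named integer vector of length `pz$L` (names = alphabet).
#' @export
assignment_digits <- function(pz, a) {
  stats::setNames(a[seq_len(pz$L)], pz$alphabet)
}

#' Numeric value of a word under an assignment
#'
#' Substitutes each letter of `word` with its assigned digit and reads the
#' result as a base-10 integer.
#'
#' @inheritParams assignment_digits
#' @param word a string over the puzzle alphabet.
#' @return a non-negative number.
#' @examples
#' pz <- parse_puzzle("DONALD+GERALD=ROBERT")
#' sol <- as_assignment(pz, c(5, 2, 6, 4, 8, 1, 9, 7, 3, 0))
#' word_value("DONALD", sol, pz)  # 526485
#' @export
word_value <- function(word, a, pz) {
  ch <- strsplit(word, "")[[1L]]
  idx <- match(ch, pz$alphabet)
  if (anyNA(idx))
    stop("word contains letters absent from the puzzle alphabet")
  n <- length(ch)
  sum(a[idx] * 10^(n - seq_len(n)))
}

#' Cost of an assignment
#'
#' The cost is `|value(result) - value(operand1) - value(operand2)|`, except
#' that assignments placing digit 0 on any leading letter are invalid and
#' receive the puzzle's `penalty_cost` (they remain part of the searchable
#' state space).  An assignment solves the puzzle iff its cost is 0.
#'
#' @inheritParams assignment_digits
#' @return a non-negative number.
#' @examples
#' pz <- parse_puzzle("DONALD+GERALD=ROBERT")
#' sol <- as_assignment(pz, c(5, 2, 6, 4, 8, 1, 9, 7, 3, 0))
#' cost(pz, sol)  # 0
#' @export
cost <- function(pz, a) {
  if (any(a[pz$leading_idx] == 0L)) return(pz$penalty_cost)
  abs(sum(pz$coef * a))
}

#' @rdname cost
#' @export
is_solution <- function(pz, a) {
  cost(pz, a) == 0
}

#' Count solutions by exhaustive enumeration
#'
#' Enumerates all `10!/(10-L)!` injective letter-to-digit maps (pruning
#' leading-zero branches, which can never be solutions) and counts those
#' with cost zero.  For the full ten-letter case this scans the 3,628,800
#' permutations in well under a second.
#'
#' @inheritParams as_assignment
#' @param limit stop counting once this many solutions are found (useful
#'   when screening for uniqueness: `limit = 2`).
#' @return number of zero-cost assignments found (capped at `limit`).
#' @examples
#' count_solutions(parse_puzzle("A+A=B"))  # 4: (1,2) (2,4) (3,6) (4,8)
#' @export
count_solutions <- function(pz, limit = Inf) {
  cpp_count_solutions(pz$coef, pz$leading_idx - 1L, pz$L, as.numeric(limit))
}

#' Find solutions by exhaustive enumeration
#'
#' @inheritParams count_solutions
#' @param max_count maximum number of solutions to return.
#' @return a list of assignments (length-10 integer vectors); empty if the
#'   puzzle has no solution.
#' @export
find_solutions <- function(pz, max_count = 10L) {
  m <- cpp_find_solutions(pz$coef, pz$leading_idx - 1L, pz$L,
                          as.integer(max_count))
  lapply(seq_len(nrow(m)), function(i) as_assignment(pz, m[i, ]))
}

#' Generate a random cryptarithmetic puzzle with a unique solution
#'
#' Produces a puzzle with exactly 10 distinct letters and exactly one
#' solution, verified by exhaustive enumeration.  Two constructions are
#' used:
#' \describe{
#'   \item{`"fill"`}{draw three words of the requested lengths with letters
#'     placed so that exactly 10 distinct letters occur, then reject unless
#'     enumeration finds exactly one solution.  Random letter sums rarely
#'     admit any solution, so this route is tried `max_rejects` times.}
#'   \item{`"letterize"`}{draw a correct numeric sum (two random
#'     `word_len`-digit numbers without leading zeros) whose digit string
#'     covers all 10 digits, map digits to random letters, and keep the
#'     puzzle if the built-in solution is the only one.  This construction
#'     guarantees at least one solution before the uniqueness screen and is
#'     used as a fallback when `"fill"` exhausts its budget.}
#' }
#'
#' @param word_len operand word length (the result may be one letter
#'   longer); default 6 as in `DONALD+GERALD=ROBERT`.
#' @param seed integer seed; the same seed always yields the same puzzle.
#' @param max_rejects rejection budget for the `"fill"` construction before
#'   falling back to `"letterize"`, and overall budget for `"letterize"`.
#' @param method `"auto"` (fill then letterize), `"fill"` or `"letterize"`.
#' @return a [parse_puzzle()] object with `count_solutions(pz) == 1`.
#' @export
random_puzzle <- function(word_len = 6L, seed = NULL, max_rejects = 200L,
                          method = c("auto", "fill", "letterize")) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  if (method %in% c("auto", "fill")) {
    for (i in seq_len(max_rejects)) {
      pz <- .fill_candidate(word_len)
      if (!is.null(pz) && count_solutions(pz, limit = 2) == 1) return(pz)
    }
    if (method == "fill")
      stop("random_puzzle: no unique-solution puzzle found in ",
           max_rejects, " attempts (method = \"fill\")")
  }
  for (i in seq_len(10L * max_rejects)) {
    pz <- .letterize_candidate(word_len)
    if (!is.null(pz) && count_solutions(pz, limit = 2) == 1) return(pz)
  }
  stop("random_puzzle: generation failed after ", 10L * max_rejects,
       " letterize attempts")
}

# random words with exactly 10 distinct letters across the three of them
.fill_candidate <- function(word_len) {
  lens <- c(word_len, word_len, word_len)
  total <- sum(lens)
  if (total < 10L) return(NULL)
  letset <- sample(LETTERS, 10L)
  # place each of the 10 letters once, fill the rest uniformly
  slots <- sample.int(total, 10L)
  fill <- character(total)
  fill[slots] <- letset
  fill[-slots] <- sample(letset, total - 10L, replace = TRUE)
  w <- c(paste(fill[seq_len(lens[1L])], collapse = ""),
         paste(fill[lens[1L] + seq_len(lens[2L])], collapse = ""),
         paste(fill[lens[1L] + lens[2L] + seq_len(lens[3L])], collapse = ""))
  pz <- tryCatch(parse_puzzle(paste0(w[1L], "+", w[2L], "=", w[3L])),
                 error = function(e) NULL)
  if (is.null(pz) || pz$L != 10L) return(NULL)
  pz
}

# correct sum first, then letterize; NULL unless all 10 digits occur
.letterize_candidate <- function(word_len) {
  lo <- 10^(word_len - 1L)
  hi <- 10^word_len - 1L
  o1 <- sample(lo:hi, 1L)
  o2 <- sample(lo:hi, 1L)
  r <- o1 + o2
  digs <- strsplit(paste0(o1, o2, r), "")[[1L]]
  if (length(unique(digs)) != 10L) return(NULL)
  map <- sample(LETTERS, 10L)
  names(map) <- as.character(0:9)
  tr <- function(x) paste(map[strsplit(as.character(x), "")[[1L]]],
                          collapse = "")
  parse_puzzle(paste0(tr(o1), "+", tr(o2), "=", tr(r)))
}
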