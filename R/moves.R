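#' Elementary move: transposition of two digit slots
#'
#' Picks two distinct slots of the 10-slot assignment uniformly at random
#' and exchanges their digits.  The move is accepted unconditionally — no
#' cost comparison is made, which is what lets the random walk explore the
#' whole state space.  When the puzzle has fewer than 10 letters a swap may
#' involve a hidden slot, which substitutes an unused digit for a visible
#' one; for ten-letter puzzles every swap exchanges two letters' digits.
#'
#' The input is not modified; a new assignment is returned.  The operator is
#' symmetric (the probability of `a -> b` equals that of `b -> a`), and the
#' probability that the next move exactly undoes this one is
#' `1/choose(10, 2) = 1/45`.
#'
#' @param a an assignment (length-10 integer vector).
#' @return a new assignment.
#' @export
elementary_move <- function(a) {
  i <- .ps_randint(10L) + 1L
  j <- .ps_randint(9L) + 1L
  if (j >= i) j <- j + 1L
  tmp <- a[i]; a[i] <- a[j]; a[j] <- tmp
  a
}

#' Global move: redraw the whole assignment
#'
#' Returns a uniformly random injective assignment, independent of the
#' current state.  This is the baseline move for which the mean rescaled
#' computational cost of the independent search equals 1.
#'
#' @param pz a [parse_puzzle()] object (determines nothing beyond context;
#'   the draw is a uniform permutation of the digits 0-9).
#' @return a new assignment.
#' @export
global_move <- function(pz) {
  .ps_shuffle(0:9)
}

#' Imitation: assimilate one digit-to-letter pairing from a model
#'
#' One letter position where target and model disagree is chosen uniformly;
#' the target adopts the model's digit there by a transposition (the digit
#' is swapped in from wherever the target currently holds it), which keeps
#' the assignment injective.  The Hamming distance between target and model
#' (over visible letters) strictly decreases: by 2 when the swap fixes both
#' positions, otherwise by 1.  The copy is accepted unconditionally even if
#' it raises the target's cost; the abort rules (target cheaper than model,
#' or identical to it) are applied upstream in [update_agent()].
#'
#' @param target,model assignments over the same puzzle; must differ on at
#'   least one visible letter.
#' @param pz the [parse_puzzle()] object.
#' @return the new target assignment.
#' @export
imitate <- function(target, model, pz) {
  L <- pz$L
  D <- which(target[seq_len(L)] != model[seq_len(L)])
  if (length(D) == 0L)
    stop("imitate() called with target identical to model")
  pos <- D[.ps_randint(length(D)) + 1L]
  dgt <- model[pos]
  r <- which(target == dgt)
  tmp <- target[pos]; target[pos] <- target[r]; target[r] <- tmp
  target
}
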