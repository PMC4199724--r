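# Shared randomness protocol.
#
# Every stochastic primitive in the package draws from R's global generator
# through these helpers, using exactly the same sequence of uniform draws as
# the compiled engine (src/search.cpp).  This is what makes
# run_search(engine = "r") and run_search(engine = "cpp") byte-identical for
# a given seed, which the test suite exploits as a cross-implementation
# check.  Draw conventions:
#   * .ps_randint(n): one uniform, floor(u * n) clamped to 0..n-1
#   * Fisher-Yates shuffles/samples always consume a draw per position,
#     including the trivial last one, so draw counts are data-independent.

.ps_randint <- function(n) {
  r <- floor(runif(1L) * n)
  if (r >= n) r <- n - 1
  as.integer(r)
}

# full in-place Fisher-Yates shuffle; length(v) draws
.ps_shuffle <- function(v) {
  m <- length(v)
  for (i in seq_len(m)) {
    j <- i + .ps_randint(m - i + 1L)
    tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
  }
  v
}

# first k of a partial Fisher-Yates: k-out-of-m sample without replacement
.ps_sample_k <- function(v, k) {
  m <- length(v)
  for (i in seq_len(k)) {
    j <- i + .ps_randint(m - i + 1L)
    tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
  }
  v[seq_len(k)]
}
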