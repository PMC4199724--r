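Package: puzzleswarm
Title: Imitative-Learning Agent-Based Search on Cryptarithmetic Puzzles
Version: 0.1.0
Authors@R:
    person("R.", "Silva", email = "rsilva@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of collective problem solving by imitative
    learning. A group of N agents searches the permutation space of a
    cryptarithmetic (alphametic) puzzle such as DONALD+GERALD=ROBERT; each
    agent either performs a local random move (a transposition of two
    digit-to-letter assignments) or, with probability p, copies one differing
    assignment from the best-performing agent among its K fixed influencers.
    The package provides puzzle encoding and exhaustive solution counting,
    the move and imitation operators, a fast compiled search engine with a
    pure-R reference implementation, summary statistics of the computational
    cost (first-passage time) distributions including exponential fits and
    leadership-stasis measures, and reproducible parameter sweeps over N, p
    and K.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
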