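test_that("parse_puzzle builds alphabet in first-occurrence order", {
  pz <- donald()
  expect_equal(pz$alphabet,
               c("D", "O", "N", "A", "L", "G", "E", "R", "B", "T"))
  expect_setequal(pz$leading_letters, c("D", "G", "R"))
  expect_equal(pz$L, 10L)
  expect_equal(pz$space_size, factorial(10))

  pz2 <- parse_puzzle("A+A=B")
  expect_equal(pz2$alphabet, c("A", "B"))
  expect_setequal(pz2$leading_letters, c("A", "B"))
  expect_equal(pz2$space_size, 90)

  # whitespace tolerated, words may share first letters
  pz3 <- parse_puzzle("  AB + AC = AD \n")
  expect_equal(pz3$leading_letters, "A")
})

test_that("parse_puzzle rejects malformed input", {
  expect_error(parse_puzzle("AB+CD=EFGHIJKLMNO"), "10 distinct letters")
  expect_error(parse_puzzle("AB-CD=EF"), "malformed")
  expect_error(parse_puzzle("ab+cd=ef"), "malformed")
  expect_error(parse_puzzle("AB+CD"), "malformed")
  expect_error(parse_puzzle("A+A=A"), "at least 2")
  # penalty must dominate every attainable valid cost
  expect_error(parse_puzzle("AB+CD=EF", penalty_cost = 100), "penalty_cost")
})

test_that("word_value substitutes digits positionally", {
  pz <- donald()
  sol <- donald_solution(pz)
  expect_equal(word_value("DONALD", sol, pz), 526485)
  expect_equal(word_value("GERALD", sol, pz), 197485)
  expect_equal(word_value("ROBERT", sol, pz), 723970)
  expect_equal(word_value("T", sol, pz), 0)
  expect_equal(word_value("AB", as_assignment(parse_puzzle("AB+BA=AA"),
                                              c(1L, 2L)),
                          parse_puzzle("AB+BA=AA")), 12)
  expect_error(word_value("XY", sol, pz), "absent")
})

test_that("cost matches hand arithmetic, penalty and zero cases", {
  pz <- donald()
  sol <- donald_solution(pz)
  expect_equal(cost(pz, sol), 0)
  expect_true(is_solution(pz, sol))

  # exchanging the digits of B and T gives |720973 - 526485 - 197485|
  swp <- sol
  bt <- match(c("B", "T"), pz$alphabet)
  swp[bt] <- swp[rev(bt)]
  expect_equal(cost(pz, swp), 2997)
  expect_false(is_solution(pz, swp))

  # any assignment with D = 0 is invalid and gets the penalty
  d0 <- as_assignment(pz, c(0L, 2L, 6L, 4L, 8L, 1L, 9L, 7L, 3L, 5L))
  expect_equal(cost(pz, d0), pz$penalty_cost)
  expect_false(is_solution(pz, d0))
})

test_that("cost is symmetric in operand order and bounded by the penalty", {
  pz1 <- parse_puzzle("DONALD+GERALD=ROBERT")
  pz2 <- parse_puzzle("GERALD+DONALD=ROBERT")
  set.seed(11)
  for (i in 1:50) {
    a <- random_assignment(pz1)
    d <- assignment_digits(pz1, a)
    a2 <- as_assignment(pz2, d[pz2$alphabet])
    expect_equal(cost(pz1, a), cost(pz2, a2))
    if (all(a[pz1$leading_idx] != 0))
      expect_lt(cost(pz1, a), pz1$penalty_cost)
  }
})

test_that("count_solutions agrees with the brute-force oracle on small puzzles", {
  # frozen values computed by the independent column-arithmetic oracle
  cases <- list(list(expr = "A+A=B", n = 4),       # (1,2) (2,4) (3,6) (4,8)
                list(expr = "A+B=AB", n = 0),
                list(expr = "ACB+ADC=BBD", n = 1),
                list(expr = "AB+BA=CC", n = NA))   # oracle-only case
  for (cs in cases) {
    pz <- parse_puzzle(cs$expr)
    got <- count_solutions(pz)
    expect_equal(got, oracle_count_solutions(cs$expr), info = cs$expr)
    if (!is.na(cs$n)) expect_equal(got, cs$n, info = cs$expr)
  }
  # limit short-circuits
  expect_equal(count_solutions(parse_puzzle("A+A=B"), limit = 2), 2)
})

test_that("find_solutions returns actual solutions", {
  pz <- small4()
  sols <- find_solutions(pz)
  expect_length(sols, 1L)
  expect_true(is_solution(pz, sols[[1]]))
  expect_equal(unname(assignment_digits(pz, sols[[1]])), c(1L, 5L, 3L, 8L))
})

test_that("assignment constructors validate and round-trip", {
  pz <- small4()
  a <- as_assignment(pz, c(1L, 5L, 3L, 8L))
  expect_equal(sort(a), 0:9)  # full permutation with hidden slots
  expect_equal(assignment_digits(pz, a),
               c(A = 1L, C = 5L, B = 3L, D = 8L))
  expect_error(as_assignment(pz, c(1L, 1L, 3L, 8L)), "distinct")
  expect_error(as_assignment(pz, c(1L, 5L, 3L)), "distinct|0..9")
  set.seed(3)
  r <- random_assignment(pz)
  expect_equal(sort(r), 0:9)
})

test_that("random_puzzle yields 10-letter unique-solution puzzles, deterministically", {
  pz1 <- random_puzzle(seed = 101)
  pz2 <- random_puzzle(seed = 101)
  expect_identical(pz1$alphabet, pz2$alphabet)
  expect_identical(pz1$operand1, pz2$operand1)
  expect_equal(pz1$L, 10L)
  expect_equal(count_solutions(pz1, limit = 2), 1)

  pz3 <- random_puzzle(seed = 77, method = "letterize")
  expect_equal(pz3$L, 10L)
  expect_equal(count_solutions(pz3, limit = 2), 1)
})
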