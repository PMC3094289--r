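test_that("the assignment solver matches brute-force enumeration", {
  set.seed(123)
  for (rep in 1:30) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    fast <- solveAssignment(cost)
    brute <- arborquant:::bruteAssignment(cost)
    expect_equal(attr(fast, "total"), attr(brute, "total"), tolerance = 1e-12)
    expect_identical(sort(fast), seq_len(n))   # a permutation
  }
})

test_that("the solver handles structured and degenerate matrices", {
  ## identity-favoring matrix assigns the diagonal
  cost <- matrix(1, 4, 4); diag(cost) <- 0
  expect_identical(as.integer(solveAssignment(cost)), 1:4)
  ## constant matrix: any permutation, total = n * c
  flat <- matrix(2, 3, 3)
  expect_equal(attr(solveAssignment(flat), "total"), 6)
  empty <- solveAssignment(matrix(numeric(0), 0, 0))
  expect_equal(attr(empty, "total"), 0)
})
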