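test_that("identical sequences align along the diagonal at zero cost", {
  a <- alignDtw(c(1, 5, 2, 8), c(1, 5, 2, 8), cost = "abs")
  expect_equal(totalCost(a), 0)
  expect_equal(alignmentPath(a),
               matrix(rep(1:4, 2), ncol = 2,
                      dimnames = list(NULL, c("reference", "query"))))
})

test_that("the printed small example has total cost 1 under absolute cost", {
  a <- alignDtw(c(1, 2, 3), c(1, 3), cost = "abs")
  expect_equal(totalCost(a), 1)
})

test_that("the cumulative-cost recursion equals brute-force path enumeration", {
  set.seed(99)
  for (trial in 1:200) {
    M <- sample(1:6, 1); N <- sample(1:6, 1)
    x <- round(rnorm(M), 2); y <- round(rnorm(N), 2)
    a <- alignDtw(x, y, cost = "squared", band = NULL)
    C <- a@costMatrix
    expect_equal(totalCost(a), bruteForceDtw(C), tolerance = 1e-10)
    ## the reported path attains the reported cost
    p <- alignmentPath(a)
    expect_equal(sum(C[p]), totalCost(a), tolerance = 1e-10)
  }
})

test_that("alignment paths are monotone with unit steps from (1,1) to (M,N)", {
  set.seed(5)
  for (trial in 1:20) {
    x <- rnorm(sample(2:10, 1)); y <- rnorm(sample(2:10, 1))
    p <- alignmentPath(alignDtw(x, y))
    expect_equal(p[1, ], c(reference = 1L, query = 1L))
    expect_equal(unname(p[nrow(p), ]), c(length(x), length(y)))
    st <- diff(p)
    expect_true(all(st >= 0 & st <= 1))
    expect_true(all(rowSums(st) >= 1))
  }
})

test_that("channel alignment recovers an injected lag to within one sample", {
  set.seed(2)
  t <- seq(0, 10, by = 1 / 100)
  ref <- sin(2 * pi * 1.3 * t) + 0.1 * rnorm(length(t))
  for (lagN in c(3, 7, 12)) {
    qry <- c(rep(ref[1], lagN), ref[1:(length(ref) - lagN)]) +
      0.1 * rnorm(length(t))
    est <- alignChannel(ref, qry)$lag
    expect_lte(abs(est - lagN), 1)
  }
})
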