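test_that("normalised adjacency matches hand computation on small graphs", {
  ## single self-looped node
  expect_equal(buildNormalizedAdjacency(skeletonGraph("a")),
               matrix(1, 1, 1, dimnames = list("a", "a")))
  ## two connected nodes: degrees 2, operator all 0.5
  g2 <- skeletonGraph(c("a", "b"))
  expect_equal(unname(buildNormalizedAdjacency(g2)),
               matrix(0.5, 2, 2))
  ## symmetry for arbitrary graphs
  set.seed(1)
  A <- matrix(rbinom(25, 1, 0.5), 5, 5)
  A <- 1 * ((A + t(A)) > 0); diag(A) <- 1
  g5 <- skeletonGraph(letters[1:5], A)
  op <- buildNormalizedAdjacency(g5)
  expect_equal(op, t(op))
  expect_lte(max(abs(eigen(op)$values)), 1 + 1e-12)
})

test_that("the graph-convolution layer composes normalisation, weights and activation", {
  g1 <- skeletonGraph("a")
  expect_equal(unname(gcnForward(matrix(3), g1, matrix(1))), matrix(3))
  ## two-node graph, H = I, W = I -> the operator itself
  g2 <- skeletonGraph(c("a", "b"))
  expect_equal(unname(gcnForward(diag(2), g2, diag(2))),
               matrix(0.5, 2, 2))
  ## ReLU zeroes all-negative pre-activations
  expect_equal(unname(gcnForward(-diag(2), g2, diag(2),
                                 activation = function(x) pmax(x, 0))),
               matrix(0, 2, 2))
  expect_error(gcnForward(matrix(1, 3, 2), g2, diag(2)), "nodes")
  expect_error(gcnForward(matrix(1, 2, 3), g2, diag(2)),
               "non-conformable")
})

test_that("the layer equals the dense matrix oracle on random graphs up to 5 nodes", {
  set.seed(7)
  for (trial in 1:40) {
    n <- sample(2:5, 1); d <- sample(1:4, 1); dOut <- sample(1:4, 1)
    A <- matrix(rbinom(n^2, 1, 0.6), n, n)
    A <- 1 * ((A + t(A)) > 0); diag(A) <- 1
    gr <- skeletonGraph(paste0("n", 1:n), A)
    H <- matrix(rnorm(n * d), n, d)
    W <- matrix(rnorm(d * dOut), d, dOut)
    Dm <- diag(rowSums(A))
    oracle <- solve(sqrt(Dm)) %*% A %*% solve(sqrt(Dm)) %*% H %*% W
    expect_equal(unname(gcnForward(H, gr, W)), oracle, tolerance = 1e-12)
  }
})

test_that("gcnForward is equivariant under node permutation", {
  set.seed(8)
  n <- 4
  A <- matrix(rbinom(n^2, 1, 0.6), n, n)
  A <- 1 * ((A + t(A)) > 0); diag(A) <- 1
  H <- matrix(rnorm(n * 3), n, 3)
  W <- matrix(rnorm(9), 3, 3)
  base <- gcnForward(H, skeletonGraph(paste0("n", 1:n), A), W)
  pm <- sample(n)
  perm <- gcnForward(H[pm, ], skeletonGraph(paste0("n", 1:n), A[pm, pm]), W)
  expect_equal(unname(perm), unname(base)[pm, ], tolerance = 1e-12)
})
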