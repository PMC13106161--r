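test_that("federated averaging is the sample-weighted mean", {
  expect_equal(fedavgAggregate(list(c(1, 2)), 5), c(1, 2))
  expect_equal(fedavgAggregate(list(0, 1), c(1, 3)), 0.75)
  ## idempotence on identical clients
  w <- rnorm(4)
  expect_equal(fedavgAggregate(list(w, w, w), c(2, 5, 9)), w)
  ## direct oracle on random updates
  set.seed(6)
  ws <- lapply(1:4, function(i) rnorm(7))
  ns <- sample(1:20, 4)
  oracle <- Reduce(`+`, Map(function(w, n) w * n / sum(ns), ws, ns))
  expect_equal(fedavgAggregate(ws, ns), oracle, tolerance = 1e-12)
  expect_error(fedavgAggregate(list(1:2, 1:3), c(1, 1)), "length")
  expect_error(fedavgAggregate(list(1, 2), c(1, 0)), "positive")
})

test_that("equal sample counts reduce aggregation to the arithmetic mean", {
  set.seed(7)
  ws <- lapply(1:5, function(i) rnorm(6))
  expect_equal(fedavgAggregate(ws, rep(3, 5)),
               Reduce(`+`, ws) / 5, tolerance = 1e-12)
})

test_that("aggregated weights are convex combinations per coordinate", {
  set.seed(8)
  ws <- lapply(1:6, function(i) rnorm(10))
  ns <- sample(1:30, 6, replace = TRUE)
  agg <- fedavgAggregate(ws, ns)
  lo <- do.call(pmin, ws); hi <- do.call(pmax, ws)
  expect_true(all(agg >= lo - 1e-12 & agg <= hi + 1e-12))
})

test_that("local fine-tuning returns a parameter increment and never raw data", {
  fw <- makeRandomWindows(n = 6, Tn = 12, seed = 9)
  mdl <- initHarModel(fw, harConfig(dModel = 8, nHeads = 2, dff = 8,
                                    dGcn = 4, subFrames = 3, seed = 1))
  up0 <- localFinetune(mdl, fw, "c1", rounds = 0)
  expect_true(all(updateDelta(up0) == 0))
  expect_equal(sampleCount(up0), 6)
  up <- localFinetune(mdl, fw, "c1", rounds = 3, lr = 0.01)
  expect_gt(sum(abs(updateDelta(up))), 0)
  ## transport schema carries parameters and counts only
  man <- updateManifest(up)
  expect_setequal(names(man), c("client_id", "n_k", "round",
                                "vector_length", "delta"))
  expect_error(localFinetune(mdl, subsetWindows(fw, integer(0)), "c"),
               "non-empty")
})

test_that("a federation round aggregates reconstructed client weights per the update rule", {
  fw <- makeRandomWindows(n = 12, Tn = 12, seed = 10)
  fw@subject <- rep(c("c1", "c2", "c3"), each = 4)
  mdl <- initHarModel(fw, harConfig(dModel = 8, nHeads = 2, dff = 8,
                                    dGcn = 4, subFrames = 3, seed = 2))
  clients <- lapply(split(seq_len(12), fw@subject),
                    function(ix) subsetWindows(fw, ix))
  w0 <- getModelParams(mdl)
  ## direct recomputation oracle
  ups <- lapply(names(clients), function(id)
    localFinetune(mdl, clients[[id]], id, rounds = 2, lr = 0.01))
  oracle <- fedavgAggregate(lapply(ups, function(u) w0 + updateDelta(u)),
                            vapply(ups, sampleCount, 0))
  server <- runRound(list(model = mdl, round = 0L, log = NULL), clients,
                     rounds = 2, lr = 0.01)
  expect_equal(getModelParams(server$model), oracle, tolerance = 1e-12)
  expect_equal(server$round, 1L)
  expect_setequal(server$log$client, c("c1", "c2", "c3"))
  ## single client: the server adopts that client's weights
  one <- runRound(list(model = mdl, round = 0L, log = NULL),
                  clients[1], rounds = 2, lr = 0.01)
  expect_equal(getModelParams(one$model), w0 + updateDelta(ups[[1]]),
               tolerance = 1e-12)
})
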