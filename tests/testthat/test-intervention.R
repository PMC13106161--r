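test_that("the clipped surrogate matches hand-evaluated cases and its bounds", {
  expect_equal(ppoSurrogate(1, 2.7, 0.2), 2.7)      # no-update point
  expect_equal(ppoSurrogate(1.5, 1, 0.2), 1.2)      # min(1.5, 1.2)
  expect_equal(ppoSurrogate(0.5, -1, 0.2), -0.8)    # min(-0.5, -0.8)
  set.seed(11)
  r <- runif(500, 0.01, 3); a <- rnorm(500)
  s <- ppoSurrogate(r, a, 0.2)
  expect_true(all(s <= r * a + 1e-12))
  expect_equal(ppoSurrogate(rep(1, 500), a, 0.2), a)
  expect_error(ppoSurrogate(-0.1, 1), "positive")
})

test_that("the goal loss is the stated weighted combination", {
  one <- function(p, s, su) 1
  g1 <- goalSpec(components = list(fMuscle = one, fFatloss = one,
                                   fFatigue = one))
  expect_equal(goalLoss(prescription(), userState(), g1), 1)
  ## the first tabulated user profile: weights (0.55, 0.30, 0.15)
  cmp <- list(fMuscle = function(p, s, su) 2,
              fFatloss = function(p, s, su) 1,
              fFatigue = function(p, s, su) 0)
  g2 <- goalSpec(weights = c(0.55, 0.30, 0.15), components = cmp)
  expect_equal(goalLoss(prescription(), userState(), g2), 1.40)
  ## degenerate weight on one component returns that component alone
  g3 <- goalSpec(weights = c(0, 0, 1),
                 components = list(fFatigue = function(p, s, su) 0.42))
  expect_equal(goalLoss(prescription(), userState(), g3), 0.42)
  gBad <- goalSpec(components = list(fMuscle = function(p, s, su) NaN))
  expect_error(goalLoss(prescription(), userState(), gBad), "fMuscle")
})

test_that("prescription optimisation respects smoothness and the candidate losses", {
  cur <- prescription(intensity = 0.5)
  cands <- list(prescription(intensity = 0.2),
                prescription(intensity = 0.5),
                prescription(intensity = 0.9))
  ## lambda -> infinity: the current prescription (a candidate) wins
  sel <- optimizePrescription(cur, goalSpec(), cands, lambda = 1e9)
  expect_equal(intensityOf(sel), 0.5)
  ## single candidate at lambda 0
  selOne <- optimizePrescription(cur, goalSpec(), cands[2], lambda = 0)
  expect_equal(intensityOf(selOne), 0.5)
  ## three candidates with precomputed losses {0.5, 0.2, 0.9}
  lossOf <- function(p, s, su)
    c(`0.2` = 0.5, `0.5` = 0.2, `0.9` = 0.9)[[as.character(intensityOf(p))]]
  gFix <- goalSpec(weights = c(1, 0, 0), components = list(fMuscle = lossOf))
  sel3 <- optimizePrescription(cur, gFix, cands, lambda = 0)
  expect_equal(intensityOf(sel3), 0.5)   # candidate 2, loss 0.2
  expect_error(optimizePrescription(cur, goalSpec(), list()), "non-empty")
})

test_that("the safety override applies the 90 percent heart-rate-maximum rule", {
  ## age 30: threshold 0.9 * 190 = 171
  hot <- userState(heartRate = 175, age = 30)
  cool <- userState(heartRate = 150, age = 30)
  prop <- prescription(intensity = 0.9)
  ovHot <- safetyOverride(prop, hot)
  expect_true(ovHot$override)
  expect_lte(intensityOf(ovHot$prescription), 0.2)
  expect_identical(ovHot$prescription@exerciseType, "recovery")
  ovCool <- safetyOverride(prop, cool)
  expect_false(ovCool$override)
  expect_identical(ovCool$prescription, prop)
  ## severe movement deformation triggers regardless of heart rate
  expect_true(safetyOverride(prop, cool, deformity = TRUE)$override)
  ## hysteresis: once active, the override persists until HR re-enters
  mid <- userState(heartRate = 165, age = 30)     # above 0.85*190 = 161.5
  expect_true(safetyOverride(prop, mid, active = TRUE)$override)
  expect_false(safetyOverride(prop, cool, active = TRUE)$override)
})

test_that("the fatigue index is a bounded monotone GSR/HRV composite", {
  set.seed(12)
  gsrFlat <- rep(2, 40); hrvFlat <- rep(60, 40)
  expect_message(fi <- fatigueIndex(gsrFlat, hrvFlat), "neutral")
  expect_equal(fi, 0.5)
  gsrUp <- seq(2, 5, length.out = 40) + rnorm(40, 0, 0.01)
  hrv <- 60 + rnorm(40, 0, 0.5)
  base <- fatigueIndex(gsrUp, hrv)
  gsrLate <- gsrUp; gsrLate[31:40] <- gsrLate[31:40] + 2   # extra late rise
  expect_gt(fatigueIndex(gsrLate, hrv), base)
  hrvDown <- seq(70, 40, length.out = 40)
  expect_gt(fatigueIndex(gsrUp, hrvDown), fatigueIndex(gsrUp, rev(hrvDown)))
  expect_gte(base, 0); expect_lte(base, 1)
  ## closed form on a grid: plogis(riseG - riseH)
  rise <- function(x) {
    q <- max(1, floor(length(x) / 4))
    (mean(tail(x, q)) - mean(head(x, q))) / sd(x)
  }
  expect_equal(fatigueIndex(gsrUp, hrvDown),
               plogis(rise(gsrUp) - rise(hrvDown)), tolerance = 1e-12)
  expect_error(fatigueIndex(numeric(0), 1:3), "non-empty")
})

test_that("baseline policies implement their documented rules", {
  s1 <- userState(heartRate = 100); s2 <- userState(heartRate = 160,
                                                   fatigueIndex = 0.5)
  ## FIS ignores state entirely
  expect_identical(baselinePolicy("FIS", s1), baselinePolicy("FIS", s2))
  ## HR below the target zone: intensity strictly increased
  cur <- prescription(intensity = 0.5)
  up <- baselinePolicy("HR-rule", userState(heartRate = 100), cur,
                       targetHr = 125)
  expect_gt(intensityOf(up), 0.5)
  dn <- baselinePolicy("HR-rule", userState(heartRate = 160), cur,
                       targetHr = 125)
  expect_lt(intensityOf(dn), 0.5)
  ## fatigue beyond the threshold switches to recovery
  rec <- baselinePolicy("Fatigue-rule", userState(fatigueIndex = 0.9),
                        threshold = 0.8)
  expect_identical(rec@exerciseType, "recovery")
  ok <- baselinePolicy("Fatigue-rule", userState(fatigueIndex = 0.3),
                       threshold = 0.8)
  expect_gt(intensityOf(ok), intensityOf(rec))
  expect_error(baselinePolicy("mystery", s1), "unknown")
})

test_that("PPO training is deterministic under a fixed seed and logs the summary quantities", {
  su <- virtualSubject()
  a <- trainPpo(su, episodes = 6, nSteps = 6, seed = 5)
  b <- trainPpo(su, episodes = 6, nSteps = 6, seed = 5)
  expect_identical(a$log, b$log)
  expect_identical(a$W, b$W)
  expect_true(all(c("episode", "reward", "mean_intensity", "overrides",
                    "injuries") %in% names(a$log)))
  expect_true(is.finite(a$rewardVariance))
  expect_gte(a$convergence, 1)
})
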