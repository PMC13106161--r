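test_that("heart rate converges to resting under sustained zero intensity", {
  su <- virtualSubject(restingHr = 64)
  pr <- prescription("rest", 30, 0, 0)
  hr <- 150
  for (i in 1:10) {
    out <- stepPhysiology(su, pr, dt = 60, heartRate = hr)
    su <- out$subject; hr <- out$state@heartRate
  }
  expect_equal(hr, 64, tolerance = 1)
})

test_that("heart rate never exceeds the theoretical maximum under maximal effort", {
  su <- virtualSubject(age = 50, restingHr = 75)
  pr <- prescription("running", 30, 1, 0)
  hr <- NULL
  for (i in 1:30) {
    out <- stepPhysiology(su, pr, dt = 60, seed = i, heartRate = hr)
    su <- out$subject; hr <- out$state@heartRate
    expect_lte(hr, 220 - 50)
    expect_gte(hr, 40)
    expect_gte(out$state@fatigueIndex, 0)
    expect_lte(out$state@fatigueIndex, 1)
  }
})

test_that("longer rest intervals between identical sets lower end-of-session fatigue", {
  run <- function(rest) {
    su <- virtualSubject()
    pr <- prescription("running", 30, 0.85, rest)
    hr <- NULL
    for (i in 1:10) {
      out <- stepPhysiology(su, pr, dt = 180, heartRate = hr)
      su <- out$subject; hr <- out$state@heartRate
    }
    su@fatigue
  }
  expect_lt(run(90), run(50))
})

test_that("repeated training raises fitness with diminishing returns", {
  su <- virtualSubject(vo2max = 41)
  pr <- prescription("running", 30, 0.7, 60)
  gains <- numeric(0)
  for (w in 1:20) {
    before <- su@vo2max
    out <- stepPhysiology(su, pr, dt = 1800, heartRate = NULL)
    su <- out$subject
    su@fatigue <- 0    # recovery between sessions
    gains <- c(gains, su@vo2max - before)
  }
  expect_gt(su@vo2max, 41)
  expect_lt(su@vo2max, 62)                 # ceiling respected
  expect_lt(gains[20], gains[1])           # diminishing returns
  expect_gt(su@enduranceReps, 23)
})
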