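test_that("sensor decomposition inverts the forward model exactly", {
  kin <- ballKinematics()
  set.seed(7)
  yaw <- rnorm(60); pitch <- rnorm(60); roll <- rnorm(60)
  v <- velocitiesFromSensors(composeBallSensors(yaw, pitch, roll, kin), kin)
  expect_equal(v$yaw, yaw)
  expect_equal(v$pitch, pitch)
  expect_equal(v$roll, roll)
  expect_equal(v$forward, kin$radius * pitch)
  # pure rotations
  vy <- velocitiesFromSensors(
    composeBallSensors(rep(2, 5), rep(0, 5), rep(0, 5), kin), kin)
  expect_equal(vy$yaw, rep(2, 5))
  expect_equal(vy$forward, rep(0, 5))
  vp <- velocitiesFromSensors(
    composeBallSensors(rep(0, 5), rep(1, 5), rep(0, 5), kin), kin)
  expect_equal(vp$yaw, rep(0, 5))
  expect_equal(vp$forward, rep(kin$radius, 5))
  # non-default geometry still inverts exactly
  kin2 <- ballKinematics(sensorAzimuths = c(20, 135))
  v2 <- velocitiesFromSensors(composeBallSensors(yaw, pitch, roll, kin2), kin2)
  expect_equal(v2$roll, roll)
})

mkVts <- function(yaw, trials, flies, time) {
  new("VelocityTraceSet", time = time, yaw = yaw, trials = trials,
      flies = flies, sampleRate = 1 / diff(time[1:2]))
}

test_that("mirror aggregation cancels direction-independent bias exactly", {
  time <- seq(-1, 1, by = 0.1)
  resp <- ifelse(time >= 0 & time <= 0.6, sin(pi * time / 0.6), 0)
  bias <- 0.4
  yaw <- rbind(resp + bias, -resp + bias, resp + bias, -resp + bias)
  trials <- data.frame(fly = 1L, trial = 1:4, label = "edge_1",
                       direction = c(1L, -1L, 1L, -1L), contrast = 1,
                       lumFg = 100)
  flies <- data.frame(fly = 1L, genotype = "control", forwardSpeed = 5)
  tr <- aggregateMirrored(mkVts(yaw, trials, flies, time))
  expect_equal(tr@traces[1, ], resp)      # bias gone, response preserved
  oneSided <- mkVts(yaw[c(1, 3), ], trials[c(1, 3), ], flies, time)
  expect_warning(aggregateMirrored(oneSided), "one-sided")
})

test_that("peak velocity is baseline-referenced and delay-windowed", {
  time <- seq(-1, 1, by = 0.01)
  flies <- data.frame(fly = 1L, genotype = "g", forwardSpeed = 5)
  mkTr <- function(trace) new("TurningResponse", time = time,
                              traces = matrix(trace, 1), flies = flies,
                              info = data.frame(fly = 1L, label = "e",
                                                contrast = 1, lumFg = 1,
                                                nTrials = 2L))
  # constant trace: peak 0 regardless of the constant (baseline subtraction)
  for (c0 in c(0, 2, -1)) {
    pk <- peakVelocity(mkTr(rep(c0, length(time))), staticDur = 0.5)
    expect_equal(pk@info$peak, 0)
    expect_equal(pk@info$baseline, c0)
  }
  # planted bump of amplitude A peaking at onset + 0.3 s
  A <- 1.7
  bump <- ifelse(time >= 0 & time <= 0.6, A * sin(pi * time / 0.6), 0)
  pk <- peakVelocity(mkTr(bump + 5), staticDur = 0.5)
  expect_equal(pk@info$peak, A, tolerance = 1e-3)
  # a deflection confined to the first 100 ms after onset is excluded
  early <- ifelse(time >= 0 & time < 0.1, 3, 0)
  pkE <- peakVelocity(mkTr(early), staticDur = 0.5)
  expect_equal(pkE@info$peak, 0)
  shortT <- new("TurningResponse", time = seq(0, 0.5, 0.01),
                traces = matrix(0, 1, 51), flies = flies,
                info = data.frame(fly = 1L, label = "e", contrast = 1,
                                  lumFg = 1, nTrials = 2L))
  expect_error(peakVelocity(shortT), "window")
})

test_that("slow walkers are rejected with a strict less-than-2 mm/s rule", {
  flies <- data.frame(fly = 1:4, genotype = "g",
                      forwardSpeed = c(1, 2, 2.5, 0.4))
  tr <- new("TurningResponse", time = 0:1, traces = matrix(0, 4, 2),
            flies = flies,
            info = data.frame(fly = 1:4, label = "e", contrast = 1,
                              lumFg = 1, nTrials = 2L))
  res <- rejectSlowFlies(tr)
  expect_setequal(res$kept@flies$fly, c(2L, 3L))  # exactly 2.0 mm/s is kept
  expect_setequal(res$rejectedFlies, c(1L, 4L))
  expect_equal(res$rejectedFraction, 0.5)
  # synthetic cohort: rejected fraction tracks pSlow
  ed <- buildEdgeProtocol("ON", nTrials = 2, seed = 1)
  vts <- simulateTurning(behaviorParams("control", pSlow = 0.25), ed,
                         nFlies = 80, seed = 3)
  agg <- peakVelocity(aggregateMirrored(vts), ed)
  frac <- rejectSlowFlies(agg)$rejectedFraction
  expect_gt(frac, 0.25 - 0.12)
  expect_lt(frac, 0.25 + 0.12)
})

test_that("turn-slope fits summarize per-fly lines as mean +/- SEM", {
  lums <- c(1, 2, 4) * 1e4
  peaks <- do.call(rbind, lapply(1:3, function(f)
    data.frame(fly = f, lum = lums, peak = f * log(lums) + 0.5)))
  sf <- fitTurnSlope(peaks)
  expect_equal(sf@perFly$a, c(1, 2, 3), tolerance = 1e-10)
  expect_equal(sf@meanSlope, 2, tolerance = 1e-10)
  expect_equal(sf@semSlope, sd(1:3) / sqrt(3), tolerance = 1e-10)
  flat <- peaks; flat$peak <- 1.2
  expect_equal(fitTurnSlope(flat)@meanSlope, 0, tolerance = 1e-12)
})

test_that("behavior pipeline recovers the presets' analytic slopes", {
  ed <- buildEdgeProtocol("ON", nTrials = 10, seed = 4)
  ep <- epochTable(ed)
  lums <- sort(unique(ep$lumFg[ep$kind == "edge_motion"]))
  imax <- iMax(ed@calibration)
  for (g in c("control", "dim_underestimating")) {
    par <- behaviorParams(g, pSlow = 0)
    vts <- simulateTurning(par, ed, nFlies = 12, seed = 21)
    tr <- peakVelocity(aggregateMirrored(vts), ed)
    info <- tr@info
    sf <- fitTurnSlope(data.frame(fly = info$fly, lum = info$lumFg,
                                  peak = info$peak))
    analytic <- unname(fitLogSlope(lums, expectedPeak(par, 1, lums, imax))["a"])
    expect_lt(abs(sf@meanSlope - analytic), 2 * sf@semSlope + 0.01)
    if (g == "dim_underestimating") expect_gt(sf@meanSlope, 0)
  }
})

test_that("rescue efficiency hits its endpoints and is affine-invariant", {
  set.seed(9)
  neg <- peakMatrix(c(0.2, 0.25, 0.3), nFlies = 6, sd = 0.01)
  pos <- peakMatrix(c(1.0, 1.1, 1.2), nFlies = 6, sd = 0.01)
  expect_equal(unname(rescueEfficiency(pos, neg, pos)), rep(1, 3))
  expect_equal(unname(rescueEfficiency(neg, neg, pos)), rep(0, 3))
  mid <- (pos[1:6, ] + neg[1:6, ]) / 2
  expect_equal(unname(rescueEfficiency(mid, neg, pos)), rep(0.5, 3))
  e0 <- rescueEfficiency(mid, neg, pos)
  expect_equal(rescueEfficiency(3 * mid + 2, 3 * neg + 2, 3 * pos + 2), e0)
  expect_error(rescueEfficiency(mid, neg, neg), "undefined")
})

test_that("the efficiency permutation test is seeded, calibrated and sensitive", {
  set.seed(31)
  neg <- peakMatrix(rep(0.2, 5), nFlies = 8, sd = 0.05)
  pos <- peakMatrix(rep(1.0, 5), nFlies = 8, sd = 0.05)
  a <- peakMatrix(rep(0.9, 5), nFlies = 10, sd = 0.05)
  b <- peakMatrix(rep(0.3, 5), nFlies = 10, sd = 0.05)
  r1 <- permutationEfficiencyTest(a, b, neg, pos, nPerm = 500, seed = 2)
  r2 <- permutationEfficiencyTest(a, b, neg, pos, nPerm = 500, seed = 2)
  expect_identical(r1@p, r2@p)                   # same seed, same p-values
  expect_true(all(r1@significant))               # planted large effect
  # identical populations split at random: no significance for this seed
  pool <- peakMatrix(rep(0.5, 5), nFlies = 20, sd = 0.05)
  r0 <- permutationEfficiencyTest(pool[1:10, ], pool[11:20, ], neg, pos,
                                  nPerm = 500, seed = 5)
  expect_false(any(r0@significant))
  expect_true(all(r0@p >= 1 / 501))              # add-one convention
  expect_error(permutationEfficiencyTest(a, b, neg, pos, nPerm = 0), "nPerm")
  expect_error(permutationEfficiencyTest(a[1, , drop = FALSE], b, neg, pos),
               "2 flies")
})
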