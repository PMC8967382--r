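test_that("registration recovers planted shifts exactly at zero noise", {
  set.seed(3)
  base <- matrix(runif(400, 0, 10), 20, 20) + 100
  nT <- 40L
  shifts <- rbind(matrix(0L, 30, 2),
                  cbind(sample(-3:3, 10, TRUE), sample(-3:3, 10, TRUE)))
  fr <- array(0, c(nT, 20, 20))
  for (t in seq_len(nT))
    fr[t, , ] <- lumicon:::translateFrame(base, shifts[t, 1], shifts[t, 2],
                                          fill = 100)
  reg <- registerStack(imageStack(fr, 10), maxShift = 4)
  expect_identical(reg$shifts, shifts)
  # already-aligned stack: all shifts zero
  fr0 <- array(rep(base, 5), c(20, 20, 5))
  fr0 <- aperm(fr0, c(3, 1, 2))
  reg0 <- registerStack(imageStack(fr0, 10), maxShift = 3)
  expect_true(all(reg0$shifts == 0L))
  # pure-noise frames: bounded shifts, no crash
  set.seed(4)
  noise <- array(rnorm(10 * 15 * 15), c(10, 15, 15))
  regN <- registerStack(imageStack(noise, 10), maxShift = 3)
  expect_true(all(abs(regN$shifts) <= 3))
})

test_that("trace extraction is background-subtracted mean intensity", {
  masks <- smallMaskSet()
  fr <- array(0, c(3, 20, 20))
  fr[1, , ] <- 5; fr[2, , ] <- 7; fr[3, , ] <- 2
  ex <- extractTraces(imageStack(fr, 10), masks)
  expect_equal(unname(rawTraces(ex)), matrix(0, 3, 3))  # uniform: roi == bg
  fr[2, 6:8, 6:8] <- 7 + 1.5   # roi 1 brighter than background
  ex2 <- extractTraces(imageStack(fr, 10), masks)
  expect_equal(rawTraces(ex2)[1, 2], 1.5)
  # background mask identical to the ROI mask -> identically zero
  same <- roiMaskSet(list(squareMask(6:8, 6:8)), squareMask(6:8, 6:8))
  expect_equal(unname(rawTraces(extractTraces(imageStack(fr, 10), same))),
               matrix(0, 1, 3))
  wrong <- roiMaskSet(list(squareMask(2:3, 2:3, h = 10L, w = 10L)),
                      squareMask(8:9, 8:9, h = 10L, w = 10L))
  expect_error(extractTraces(imageStack(fr, 10), wrong), "shape")
})

test_that("dF/F honors both baseline modes and rejects degenerate baselines", {
  rts <- rtsFromMatrix(matrix(c(1, 3, 1, 3), 1), rate = 1)
  d <- computeDff(rts)             # F0 = 2 (whole-trace mean)
  expect_equal(unname(dffTraces(d)[1, ]), c(-0.5, 0.5, -0.5, 0.5))
  dConst <- computeDff(rtsFromMatrix(matrix(5, 1, 6)))
  expect_true(all(dffTraces(dConst) == 0))
  # adaptation mode uses only the stated window
  rts2 <- rtsFromMatrix(matrix(c(2, 2, 4, 8), 1), rate = 1)
  d2 <- computeDff(rts2, "adaptation_mean", window = c(0, 2))
  expect_equal(unname(dffTraces(d2)[1, ]), c(0, 0, 1, 3))
  expect_error(computeDff(rtsFromMatrix(matrix(c(-1, 1), 1))), "degenerate")
  # dF/F is invariant to rescaling raw fluorescence
  raw <- matrix(rnorm(40, 10), 2)
  expect_equal(dffTraces(computeDff(rtsFromMatrix(3.7 * raw))),
               dffTraces(computeDff(rtsFromMatrix(raw))))
})

test_that("trial averaging aligns, interpolates and cancels paired noise", {
  fl <- shortFlashes(60)               # 6 flashes of 10 s
  tl <- protocolTimeline(fl)
  rate <- 10
  tt <- seq(0, totalDuration(fl) - 1 / rate, by = 1 / rate)
  # constant trace -> constant averages
  cst <- computeDff(rtsFromMatrix(matrix(5 + 0 * tt, 1), rate = rate))
  avg <- trialAverage(cst, fl)
  expect_true(all(vapply(avg@traces, function(m) all(m == 0), logical(1))))
  # repeated label with +e / -e noise: noise cancels exactly
  lab <- names(which(table(tl$label) >= 2))[1]
  occ <- which(tl$label == lab)[1:2]
  clean <- sin(tt / 3)
  e <- numeric(length(tt))
  sel1 <- tt >= tl$tStart[occ[1]] & tt < tl$tEnd[occ[1]]
  sel2 <- tt >= tl$tStart[occ[2]] & tt < tl$tEnd[occ[2]]
  stopifnot(sum(sel1) == sum(sel2))
  e[sel1] <- 0.3; e[sel2] <- -0.3
  raw <- matrix(10 * (1 + clean + e), 1)
  rawClean <- matrix(10 * (1 + clean), 1)
  avgN <- trialAverage(computeDff(rtsFromMatrix(raw, rate = rate)), fl)
  avgC <- trialAverage(computeDff(rtsFromMatrix(rawClean, rate = rate)), fl)
  twoOcc <- avgN@traces[[lab]][, seq_len(sum(sel1))]
  # the two noisy presentations average to the clean mean (same F0: means equal)
  expect_equal(mean(avgN@traces[[lab]]), mean(avgC@traces[[lab]]),
               tolerance = 1e-10)
  # single-repetition label: average equals the interpolated trace
  single <- names(which(table(tl$label) == 1))
  if (length(single)) {
    r <- which(tl$label == single[1])
    d <- computeDff(rtsFromMatrix(rawClean, rate = rate))
    direct <- approx(tt, dffTraces(d)[1, ],
                     xout = tl$tStart[r] +
                       seq(0, 10 - 1e-9, by = 1 / rate), rule = 2)$y
    avg1 <- trialAverage(d, fl)
    expect_equal(unname(avg1@traces[[single[1]]][1, ]), direct)
  }
  expect_equal(unname(avgN@nTrials[lab]), sum(tl$label == lab))
})

test_that("polarity filter keeps lamina-like ROIs and rejects inverted or flat ones", {
  fl <- shortFlashes(80)
  rts <- simulateLmc(lmcParams("L1", pOffscreen = 0.4, noiseSd = 0.02), fl,
                     nFlies = 4, roisPerFly = 5, seed = 9)
  flt <- filterRois(computeDff(rts), fl)
  off <- roiInfo(rts)$offscreen
  expect_true(all(!roiInfo(flt$kept)$offscreen))   # inverted ROIs rejected
  expect_equal(flt$nRejected, sum(off))            # normal ROIs all kept
  # constant trace: undefined correlation -> rejected and flagged NA
  cst <- computeDff(rtsFromMatrix(matrix(4, 1, 800), rate = 10))
  fltC <- filterRois(cst, fl)
  expect_true(is.na(fltC$rho[1]))
  expect_equal(fltC$nRejected, 1L)
})

test_that("staircase step responses grow with the Weber magnitude of the step", {
  st <- buildStaircase(nRepeats = 2)
  rts <- simulateLmc(lmcParams("L2", noiseSd = 0, pOffscreen = 0), st,
                     nFlies = 1, roisPerFly = 1, seed = 1,
                     flyGainSd = 0, roiGainSd = 0)
  avg <- trialAverage(computeDff(rts), st)
  resp <- staircaseStepResponse(avg, st)
  resp <- resp[order(abs(resp$weber)), ]
  expect_equal(nrow(resp), 4L)
  expect_true(all(diff(resp$response) > 0))
  # arithmetic: max within step minus mean of last 2 s of previous epoch
  respN <- staircaseStepResponse(avg, st, normalize = TRUE)
  expect_true(all(respN$response >= 0 & respN$response <= 1))
  # constant trace -> all step responses zero
  rate <- 10
  cst <- computeDff(rtsFromMatrix(matrix(7, 1, totalDuration(st) * rate),
                                  rate = rate))
  expect_true(all(staircaseStepResponse(trialAverage(cst, st), st)$response == 0))
  # epochs shorter than the 2 s window are refused
  st1 <- buildStaircase(stepDuration = 1, nRepeats = 1)
  cst1 <- computeDff(rtsFromMatrix(matrix(7 + 1e-6 * seq_len(totalDuration(st1) * rate),
                                          1), rate = rate))
  expect_error(staircaseStepResponse(trialAverage(cst1, st1), st1), "window")
})

test_that("plateau responses subtract the brightest epoch and vanish for L2", {
  fl <- buildRandomFlashes(totalDuration = 150, seed = 3)
  l2 <- simulateLmc(lmcParams("L2", noiseSd = 0, pOffscreen = 0), fl,
                    nFlies = 1, roisPerFly = 2, seed = 1,
                    flyGainSd = 0, roiGainSd = 0)
  avg <- trialAverage(computeDff(l2), fl)
  plRaw <- plateauResponses(avg, fl, subtractHighest = FALSE)
  # no sustained component: plateaus carry no luminance dependence (they sit
  # at the common dF/F offset set by the whole-trace F0)
  expect_lt(diff(range(plRaw$plateau)), 0.01)
  pl <- plateauResponses(avg, fl, subtractHighest = TRUE)
  top <- pl[pl$lum == max(pl$lum), "plateau"]
  expect_true(all(top == 0))
})

test_that("A/B step metrics isolate contrast (peaks) and luminance (sustained)", {
  ab <- buildAbProtocol(nRepeats = 2, seed = 2)
  # transient-dominated cell: peak tracks the Weber contrast of the step,
  # so the seven -25% B steps give indistinguishable peaks
  tOnly <- lmcParams("custom", wC = 1, wL = 0, noiseSd = 0, pOffscreen = 0)
  rtsT <- simulateLmc(tOnly, ab, nFlies = 1, roisPerFly = 1, seed = 1,
                      flyGainSd = 0, roiGainSd = 0)
  avgT <- trialAverage(computeDff(rtsT, "adaptation_mean", window = c(0, 30)), ab)
  resT <- abResponses(avgT, ab)
  bP <- resT$peak[resT$type == "B"]; aP <- resT$peak[resT$type == "A"]
  expect_lt(diff(range(bP)) / max(abs(bP)), 0.05)
  expect_gt(diff(range(aP)) / max(abs(aP)), 0.5)  # A contrasts do differ
  # L1 (with a sustained component): sustained responses monotone in luminance
  rts <- simulateLmc(lmcParams("L1", noiseSd = 0, pOffscreen = 0), ab,
                     nFlies = 1, roisPerFly = 1, seed = 1,
                     flyGainSd = 0, roiGainSd = 0)
  avg <- trialAverage(computeDff(rts, "adaptation_mean", window = c(0, 30)), ab)
  res <- abResponses(avg, ab)
  aRes <- res[res$type == "A", ]
  aRes <- aRes[order(aRes$lum), ]
  expect_true(all(diff(aRes$sustained) < 0))  # sustained monotone in luminance
  # constant trace -> all metrics zero
  rate <- 10
  cst <- computeDff(rtsFromMatrix(matrix(2, 1, totalDuration(ab) * rate),
                                  rate = rate))
  resC <- abResponses(trialAverage(cst, ab), ab)
  expect_true(all(resC$peak == 0 & resC$sustained == 0))
})

test_that("edge responses measure the darkness-to-minimum deflection", {
  p <- buildEdgeProtocol("ON_imaging", nTrials = 4, seed = 2)
  rts <- simulateLmc(lmcParams("L1", noiseSd = 0, pOffscreen = 0), p,
                     nFlies = 1, roisPerFly = 3, seed = 1,
                     flyGainSd = 0, roiGainSd = 0)
  avg <- trialAverage(computeDff(rts), p)
  er <- edgeResponse(avg, p)
  byLum <- tapply(er$response, er$lum, mean)
  # response amplitude scales with edge luminance
  expect_true(all(diff(as.numeric(byLum)) > 0))
  # planted deflection of known depth
  rate <- 10
  n <- totalDuration(p) * rate
  raw <- matrix(10, 1, n)
  tl <- protocolTimeline(p)
  mot <- tl[tl$kind == "edge_motion", ][1, ]
  motOcc <- tl[tl$label == mot$label, ]
  for (r in seq_len(nrow(motOcc))) {   # plant the dip in every presentation
    dip <- which(abs((seq_len(n) - 1) / rate - (motOcc$tStart[r] + 0.35)) <= 0.16)
    raw[1, dip] <- 10 * (1 - 0.4)      # 40% dip, wide enough for the 10 Hz grid
  }
  avgP <- trialAverage(computeDff(rtsFromMatrix(raw, rate = rate)), p)
  erP <- edgeResponse(avgP, p)
  darkMean <- mean(avgP@traces[["iti"]][1, ])
  planted <- abs(darkMean - min(avgP@traces[[mot$label]][1, ]))
  expect_equal(erP$response[erP$label == mot$label], planted)
  expect_gt(planted, 0.3)
})

test_that("movie -> register -> extract -> dF/F reproduces the generator responses", {
  fl <- shortFlashes(50)
  rts <- simulateLmc(lmcParams("L1", noiseSd = 0, pOffscreen = 0), fl,
                     nFlies = 1, roisPerFly = 3, seed = 2)
  masks <- smallMaskSet()
  nT <- ncol(cleanTraces(rts))
  set.seed(6)
  shifts <- rbind(matrix(0L, 30, 2),
                  cbind(sample(-3:3, nT - 30, TRUE),
                        sample(-3:3, nT - 30, TRUE)))
  mv <- simulateMovie(cleanTraces(rts), masks, shifts = shifts, noiseSd = 0,
                      seed = 5)
  reg <- registerStack(mv$stack, maxShift = 4)
  expect_identical(reg$shifts, shifts)
  ex <- extractTraces(reg$stack, masks)
  for (i in 1:3) {
    fit <- lm(rawTraces(ex)[i, ] ~ cleanTraces(rts)[i, ])
    # recovered traces match ground truth up to an affine map
    expect_lt(max(abs(residuals(fit))), 1e-8)
  }
  # and the dF/F pipelines agree up to an affine map of the responses
  dMovie <- dffTraces(computeDff(ex))
  dTrue <- dffTraces(computeDff(rts))
  for (i in 1:3)
    expect_gt(cor(dMovie[i, ], dTrue[i, ]), 0.99999)
})
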