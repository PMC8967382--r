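test_that("contrast definitions match their closed forms and bounds", {
  expect_equal(michelsonContrast(0.98e4, 0), 1)
  expect_equal(michelsonContrast(5, 5), 0)
  expect_equal(michelsonContrast(10 / 15, 4 / 15), 3 / 7)  # the 43% epoch
  expect_error(michelsonContrast(0, 0), "undefined")

  expect_equal(weberContrast(0.75 * 7, 7), -0.25)
  expect_equal(weberContrast(3, 3), 0)
  expect_equal(weberContrast(0, 9), -1)
  expect_error(weberContrast(1, 0), "undefined")

  # antisymmetry and bounds over random luminance pairs
  set.seed(11)
  a <- runif(200, 0, 1e5); b <- runif(200, 1e-3, 1e5)
  cm <- michelsonContrast(a, b)
  expect_true(all(cm >= -1 & cm <= 1))
  expect_equal(cm, -michelsonContrast(b, a))
})

test_that("photometric calibration is linear and matches the measured anchor", {
  cal <- Calibration()
  expect_equal(cdToPhotons(51.34, cal, attenuate = FALSE), 11.77e5)
  expect_equal(cdToPhotons(0, cal), 0)
  expect_equal(cdToPhotons(2 * 12.3, cal), 2 * cdToPhotons(12.3, cal))
  expect_error(cdToPhotons(-1, cal), "0")
  expect_equal(iMax(cal), 14.71e4)
  # nominal ND mode differs from the measured attenuation
  expect_gt(iMax(Calibration(nominalNd = TRUE)), iMax(cal))
})

test_that("LED quantization moves any fraction by at most half a level", {
  cal <- Calibration()
  f <- runif(500)
  expect_true(all(abs(ledFraction(f, cal) - f) <= 1 / 30 + 1e-12))
  expect_error(ledFraction(1.2, cal), "outside")
})

test_that("ON edge set reproduces the photon-flux quintet at full contrast", {
  p <- buildEdgeProtocol("ON", nTrials = 4, seed = 1)
  ep <- epochTable(p)
  mot <- ep[ep$kind == "edge_motion" & ep$direction == 1, ]
  expect_equal(sort(mot$lumFg), c(0.98, 1.96, 3.92, 7.84, 14.71) * 1e4,
               tolerance = 1e-2)
  expect_equal(michelsonContrast(mot$lumFg, mot$lumBg), rep(1, 5))
  expect_equal(p@arenaSpan / p@nEdges, 48)  # per-edge azimuthal coverage
})

test_that("edge protocols are mirrored, seeded and duration-consistent", {
  p <- buildEdgeProtocol("ON", nTrials = 6, seed = 5)
  tl <- protocolTimeline(p)
  mot <- tl$label[grepl("^edge", tl$label)]
  counts <- table(mot)
  expect_true(all(counts == counts[1]))           # balanced levels
  byDir <- table(sub(".*_", "", mot))
  expect_equal(unname(byDir["R"]), unname(byDir["L"]))  # mirrored
  expect_identical(presentationOrder(p),
                   presentationOrder(buildEdgeProtocol("ON", nTrials = 6, seed = 5)))
  expect_false(identical(presentationOrder(p),
                         presentationOrder(buildEdgeProtocol("ON", nTrials = 6, seed = 6))))
  expect_equal(totalDuration(p), sum(epochTable(p)$duration[presentationOrder(p)]))
  expect_equal(max(tl$tEnd), totalDuration(p))
  expect_error(buildEdgeProtocol("ON", nTrials = 5), "even")
})

test_that("mixed-contrast set reproduces the printed seven percentages", {
  p <- buildEdgeProtocol("mixed", nTrials = 2, seed = 1)
  ep <- epochTable(p)
  mot <- ep[ep$kind == "edge_motion" & ep$direction == 1, ]
  expect_equal(sort(round(100 * michelsonContrast(mot$lumFg, mot$lumBg))),
               c(11, 25, 33, 43, 67, 82, 100))
  # inter-trial screen as bright as the edge
  expect_equal(ep$lumBg[ep$kind == "interval"], unique(mot$lumFg))
})

test_that("staircase exposes the expected OFF-step Weber magnitudes", {
  p <- buildStaircase(nRepeats = 1)
  expect_length(presentationOrder(p), 9L)  # 5 up (incl. start) + 4 down
  ep <- epochTable(p)
  lev <- ep$lumFg[presentationOrder(p)]
  downs <- which(diff(lev) < 0) + 1L
  mags <- abs(weberContrast(lev[downs], lev[downs - 1L]))
  expect_equal(mags, c(0.25, 1 / 3, 0.5, 1))
  expect_error(buildStaircase(levels = c(1, 0.5, 0)), "ascending")
})

test_that("random flashes are seeded, sized and near-uniform", {
  p1 <- buildRandomFlashes(totalDuration = 300, seed = 9)
  p2 <- buildRandomFlashes(totalDuration = 300, seed = 9)
  expect_identical(presentationOrder(p1), presentationOrder(p2))
  expect_length(presentationOrder(p1), 30L)
  expect_true(all(seq_len(5) %in% presentationOrder(p1)))
  long <- buildRandomFlashes(totalDuration = 1e5, seed = 3)
  counts <- table(presentationOrder(long))
  expect_lte(max(counts) - min(counts), 5)  # near-uniform level frequencies
})

test_that("A/B protocol yields exactly -25% Weber B steps in randomized pairs", {
  p <- buildAbProtocol(seed = 4)
  ep <- epochTable(p)
  aLum <- ep$lumFg[grepl("^A_", ep$label)]
  bLum <- ep$lumFg[grepl("^B_", ep$label)]
  expect_length(aLum, 7L)
  expect_equal(weberContrast(bLum, aLum), rep(-0.25, 7))
  # every A epoch is immediately followed by its B epoch
  tl <- protocolTimeline(p)
  aPos <- grep("^A_", tl$label)
  expect_equal(tl$label[aPos + 1L], sub("^A", "B", tl$label[aPos]))
  p0 <- buildAbProtocol(bWeber = 0)
  ep0 <- epochTable(p0)
  expect_equal(ep0$lumFg[grepl("^B_", ep0$label)],
               ep0$lumFg[grepl("^A_", ep0$label)])
  expect_error(buildAbProtocol(aFractions = c(0.5, 0)), "undefined B")
})

test_that("receptive-field luminance honors edge crossings and resets", {
  p <- buildEdgeProtocol("ON", nTrials = 2, seed = 1)
  tl <- protocolTimeline(p)
  firstMot <- tl[grepl("^edge", tl$label), ][1, ]
  # edge starting 16 deg away at 160 deg/s crosses at 0.1 s after onset
  rf <- rfLuminance(p, 16, sampleRate = 200)
  pre <- rf$luminance[rf$time >= firstMot$tStart & rf$time < firstMot$tStart + 0.099]
  post <- rf$luminance[rf$time >= firstMot$tStart + 0.101 &
                       rf$time < firstMot$tStart + 0.25]
  edgeLum <- epochTable(p)$lumFg[firstMot$idx]
  expect_true(all(pre == 0))
  expect_true(all(post == edgeLum))
  # rf exactly at the edge start position switches at t = 0
  rf0 <- rfLuminance(p, 0, sampleRate = 200)
  at0 <- rf0$luminance[abs(rf0$time - firstMot$tStart) < 1e-9]
  expect_equal(at0, edgeLum)
  # full-field flash protocols give the flash level at any azimuth
  fp <- shortFlashes(40)
  rff <- rfLuminance(fp, 10, sampleRate = 50)
  tlf <- protocolTimeline(fp)
  lev <- epochTable(fp)$lumFg[tlf$idx[1]]
  expect_true(all(rff$luminance[rff$time < tlf$tEnd[1]] == lev))
  expect_error(rfLuminance(p, 500), "arena")
})

test_that("protocols survive a JSON round trip", {
  p <- buildEdgeProtocol("mixed", nTrials = 2, seed = 7)
  f <- tempfile(fileext = ".json")
  writeProtocol(p, f)
  q <- readProtocol(f)
  expect_equal(q@epochs, p@epochs)
  expect_identical(q@presentation, p@presentation)
  expect_equal(iMax(q@calibration), iMax(p@calibration))
  expect_equal(totalDuration(q), totalDuration(p))
})
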