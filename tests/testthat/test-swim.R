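# Unit-level checks of the swimming pipeline at reduced granule counts;
# the full-scale readability indices live in the acceptance suite.

test_that("pooling weights are uniform by default and taper on request", {
  cfg <- defaultCfg
  expect_equal(stripPoolingWeights(cfg), rep(1, cfg@nMicrostrips))
  tapered <- stripPoolingWeights(networkConfig(distalTaperMin = 0.5))
  expect_equal(tapered[21], 1)
  expect_equal(tapered[1], 0.5)
  expect_equal(tapered[41], 0.5)
  expect_equal(tapered, rev(tapered))
  expect_true(all(diff(tapered[1:21]) > 0))
})

test_that("a swim snapshot carries the commanded wave and 50 DCN outputs", {
  cfg <- defaultCfg
  sn <- runSwimSnapshot(0.25, phase = 1.1, cfg, seed = 131,
    nPerField = 400L)
  expect_length(dcnOutputs(sn), cfg@dcnGroupSize)
  expect_length(sn@stripMeanHz, cfg@nMicrostrips)
  # realised strip means trace the commanded quarter sine
  i <- seq_len(cfg@nMicrostrips) - 1
  commanded <- 175 + 125 * sin(1.1 + 2 * pi * 0.25 * i / 40)
  expect_gt(cor(sn@stripMeanHz, commanded), 0.99)
  # output synchrony: DCN spread far below within-strip input spread
  expect_lt(sd(dcnOutputs(sn)),
    sd(normalizeHz(drawRates(rateSpec("normal", mean = 175, sd = 25),
      1e4, seed = 1), cfg)) / 5)
  expect_error(runSwimSnapshot(0, 0, cfg), "\\(0, 1\\]")
  expect_error(phaseSweep(1, nPhases = 3, cfg), "at least 4")
})

test_that("zero-amplitude input reproduces the constant-input baseline", {
  cfg <- defaultCfg
  a <- runSwimSnapshot(1, 0, cfg, seed = 132, ampHz = 0, nPerField = 400L)
  b <- runSwimSnapshot(1, pi / 2, cfg, seed = 132, ampHz = 0,
    nPerField = 400L)
  # with no commanded modulation the phase is immaterial
  expect_equal(mean(dcnOutputs(a)), mean(dcnOutputs(b)), tolerance = 0.02)
  expect_equal(sd(a@stripMeanHz), sd(b@stripMeanHz), tolerance = 0.5)
})

test_that("opposite phases mirror the output around the baseline", {
  cfg <- defaultCfg
  gain <- runSwimSnapshot(0.25, 0, cfg, seed = 133, nPerField = 400L)@gain
  up <- runSwimSnapshot(0.25, pi / 2, cfg, seed = 134, gain = gain,
    nPerField = 400L)
  down <- runSwimSnapshot(0.25, 3 * pi / 2, cfg, seed = 135, gain = gain,
    nPerField = 400L)
  mid <- runSwimSnapshot(0.25, 0, cfg, seed = 136, gain = gain,
    ampHz = 0, nPerField = 400L)
  m <- mean(dcnOutputs(mid))
  rise <- mean(dcnOutputs(up)) - m
  fall <- m - mean(dcnOutputs(down))
  # the linear chain sends phase + pi to the reflected output (mild
  # compression near the rate ceiling tolerated)
  expect_lt(abs(rise - fall), 0.3 * abs(rise))
  expect_gt(rise, 0)
  expect_gt(fall, 0)
})
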