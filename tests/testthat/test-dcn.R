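test_that("spike generation respects the shared discharge probability", {
  expect_equal(sum(spikes(generateRaster(5, rep(0, 100), seed = 111))), 0)
  expect_true(all(spikes(generateRaster(5, rep(1000, 100),
    seed = 112)) == 1L))
  expect_error(generateRaster(5, rep(1200, 10)), "probability")
  expect_error(generateRaster(0, rep(100, 10)), "positive")
  # binomial oracle: 45 afferents at 300 Hz over 10^4 ms
  ra <- generateRaster(45, rep(300, 1e4), seed = 113)
  tot <- sum(spikes(ra))
  expected <- 45 * 0.3 * 1e4
  sdB <- sqrt(45 * 1e4 * 0.3 * 0.7)
  expect_lt(abs(tot - expected), 3 * sdB)
})

test_that("convergence and smoothing preserve counts and degenerate cleanly", {
  ra <- generateRaster(1, rep(200, 500), seed = 114)
  tr1 <- convergeAndSmooth(ra, 1)
  expect_equal(tr1@smoothed, tr1@combined)
  expect_equal(tr1@combined, as.numeric(spikes(ra)[1, ]))
  # a window covering every bin from any centre returns the overall mean
  trAll <- convergeAndSmooth(ra, 2 * 500)
  expect_equal(trAll@smoothed, rep(mean(tr1@combined), 500))
  expect_error(convergeAndSmooth(ra, 0.5), "at least 1")
  # spike-count conservation through the readout
  ra45 <- generateRaster(45, sinusoidalRateCurve(250), seed = 115)
  tr <- convergeAndSmooth(ra45, 2)
  expect_equal(sum(tr@combined), sum(spikes(ra45)))
  expect_equal(tr@expected, 45 * probCurve(ra45) / 1000)
  # at a constant 300 Hz the combined rate approaches 13,500 spikes/s
  cst <- convergeAndSmooth(generateRaster(45, rep(300, 1e4), seed = 116), 2)
  se <- sqrt(45 * 0.3 * 0.7 / 1e4) * 1000
  expect_lt(abs(mean(cst@combined) * 1000 - 13500), 3 * se)
})

test_that("readout reliability grows with convergence and smoothing", {
  curve <- sinusoidalRateCurve(250, 30, 300)
  df <- reliabilityCurve(c(5, 15, 45), curve, cycles = 6,
    nReplicates = 6, seed = 117)
  expect_true(all(diff(df$corRaw) > 0))
  expect_true(all(df$corSmoothed >= df$corRaw))
  # law of large numbers: huge convergence makes replicates identical
  big <- reliabilityCurve(2000, curve, cycles = 4, nReplicates = 3,
    seed = 118)
  expect_gt(big$corSmoothed, 0.995)
  expect_error(reliabilityCurve(10, curve, nReplicates = 1), "2 replicate")
})

test_that("relative readout noise falls with ratio and smoothing", {
  curve <- rep(sinusoidalRateCurve(500, 30, 300), 10)
  tr15 <- convergeAndSmooth(generateRaster(15, curve, seed = 119), 2)
  tr45 <- convergeAndSmooth(generateRaster(45, curve, seed = 120), 2)
  expect_lt(relativeDeviation(tr45, smoothed = TRUE),
    relativeDeviation(tr15, smoothed = FALSE))
  expect_lt(relativeDeviation(tr45, smoothed = TRUE),
    relativeDeviation(tr45, smoothed = FALSE))
})

test_that("DCN group rates invert and narrow the Purkinje population", {
  cfg <- defaultCfg
  expect_equal(dcnGroupRates(rep(0.3, 400), cfg, seed = 121),
    rep(0.7, cfg@dcnGroupSize))
  set.seed(122)
  pc <- 0.5 + 0.05 * stats::rnorm(400)
  d <- dcnGroupRates(pc, cfg, seed = 123)
  expect_length(d, cfg@dcnGroupSize)
  expect_lt(sd(d), sd(pc))
  # CLT oracle at the mean sample size
  expect_lt(sd(d), 2 * sd(pc) / sqrt(cfg@pcPerDcn[1]))
  # two seeds give indistinguishable group distributions
  d2 <- dcnGroupRates(pc, cfg, seed = 124)
  expect_gt(suppressWarnings(stats::ks.test(d, d2))$p.value, 0.01)
  expect_error(dcnGroupRates(numeric(0), cfg), "empty")
})
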