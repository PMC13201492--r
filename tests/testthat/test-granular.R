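test_that("constant input passes through the Golgi conversion unchanged", {
  cfg <- defaultCfg
  rates <- rep(200, mfPerStrip(cfg))
  strip <- deriveFieldRates(rates, cfg, seed = 31)
  go <- golgiConversion(strip, cfg, seed = 32)
  want <- normalizeHz(200, cfg)
  expect_true(all(abs(unlist(glomInhibition(go)) - want) < 1e-12))
  expect_true(all(abs(unlist(go@golgiRates) - want) < 1e-12))
})

test_that("each Golgi sampling stage narrows, matching a brute-force oracle", {
  cfg <- defaultCfg
  strip <- smallStrip(cfg, seed = 33)
  go <- golgiConversion(strip, cfg, seed = 34)
  mossy <- normalizeHz(unlist(fieldRates(strip)), cfg)
  sdDend <- sd(unlist(go@dendriticMeans))
  sdSoma <- sd(unlist(go@golgiRates))
  sdGlom <- sd(unlist(go@glomInhibition))
  expect_lt(sdGlom, sdSoma)
  expect_lt(sdSoma, sdDend)
  expect_lt(sdDend, sd(mossy))
  # linear coupling of the means on the normalized scale
  expect_lt(abs(mean(unlist(go@glomInhibition)) - mean(mossy)), 0.01)
  # narrowing ratios within 10% of the brute-force resampling oracle
  set.seed(35)
  oracle <- golgiNarrowingOracle(mossy, cfg)
  expect_lt(abs(sdDend / sd(mossy) - oracle["dend"] / sd(mossy)),
    0.1 * oracle["dend"] / sd(mossy))
  expect_lt(abs(sdSoma / sdDend - oracle["soma"] / oracle["dend"]),
    0.1 * oracle["soma"] / oracle["dend"])
  expect_lt(abs(sdGlom / sdSoma - oracle["glom"] / oracle["soma"]),
    0.15 * oracle["glom"] / oracle["soma"])
})

test_that("a twin-peaked input yields near-normal glomerular inhibition", {
  cfg <- defaultCfg
  rates <- drawRates(rateSpec("bimodal", peaks = c(100, 250), sd = 25),
    mfPerStrip(cfg), seed = 36)
  strip <- deriveFieldRates(rates, cfg, seed = 37)
  go <- golgiConversion(strip, cfg, seed = 38)
  mid <- glomInhibition(go)[[50]]
  # the input is strongly bimodal ...
  expect_lt(stats::shapiro.test(
    sample(normalizeHz(rates, cfg), 500))$p.value, 0.01)
  # ... the output is not distinguishable from normal
  expect_gt(stats::shapiro.test(mid)$p.value, 0.01)
  expect_error(golgiConversion(manualStrip(list(1:10 * 10, 1:10 * 10)),
    cfg), "3 fields")
})

test_that("granule activation matches exact enumeration on a tiny field", {
  cfg <- defaultCfg
  # 8 glomeruli carrying 8 distinct mossy rates, uniform inhibition
  ratesHz <- c(60, 90, 120, 150, 180, 210, 260, 290)
  fields <- list(ratesHz, ratesHz, ratesHz)
  strip <- manualStrip(fields)
  inh <- new("GolgiOutput",
    dendriticMeans = rep(list(numeric(0)), 3),
    golgiRates = rep(list(rep(0.5, 10)), 3),
    glomInhibition = rep(list(rep(0.5, 8)), 3))
  gain <- 1.0
  oracle <- granuleEnumOracle(normalizeHz(ratesHz, defaultCfg),
    rep(0.5, 8), seq_len(8), gain)
  gr <- granuleActivation(strip, inh, gain, cfg, seed = 39,
    nPerField = 20000L, fields = 2L)
  expect_lt(abs(mean(activeFraction(gr)) - oracle$pFire), 0.01)
  expect_lt(abs(mean(unlist(activeRates(gr))) - oracle$meanRate), 0.01)
})

test_that("gain limits give all-or-none activation", {
  cfg <- defaultCfg
  strip <- smallStrip(cfg, seed = 40)
  go <- golgiConversion(strip, cfg, seed = 41)
  free <- granuleActivation(strip, go, 0, cfg, seed = 42,
    nPerField = 500L, fields = 1:10)
  expect_gt(mean(activeFraction(free)), 0.99)
  shut <- granuleActivation(strip, go, 50, cfg, seed = 43,
    nPerField = 500L, fields = 1:10)
  expect_equal(mean(activeFraction(shut)), 0)
  expect_error(granuleActivation(strip, go, -1, cfg), "non-negative")
})

test_that("gain calibration reaches dense and sparse targets", {
  cfg <- defaultCfg
  strip <- smallStrip(cfg, seed = 44)
  go <- golgiConversion(strip, cfg, seed = 45)
  g30 <- calibrateGain(strip, go, 0.30, cfg, seed = 46, nPerField = 2000L)
  gr30 <- granuleActivation(strip, go, g30, cfg, seed = 47,
    nPerField = 2000L)
  expect_gt(mean(activeFraction(gr30)), 0.27)
  expect_lt(mean(activeFraction(gr30)), 0.33)
  g1 <- calibrateGain(strip, go, 0.01, cfg, seed = 46, nPerField = 4000L)
  gr1 <- granuleActivation(strip, go, g1, cfg, seed = 48,
    nPerField = 4000L)
  expect_gt(mean(activeFraction(gr1)), 0.009)
  expect_lt(mean(activeFraction(gr1)), 0.011)
  # sparser codes need stronger inhibition
  expect_gt(g1, g30)
  # an unreachable target errors with diagnostics: at the rate floor no
  # input can ever dominate
  floorStrip <- deriveFieldRates(rep(cfg@mossyRateMinHz, mfPerStrip(cfg)),
    cfg, seed = 49)
  floorGo <- golgiConversion(floorStrip, cfg, seed = 50)
  expect_error(calibrateGain(floorStrip, floorGo, 0.5, cfg, seed = 51,
    nPerField = 100L, fields = 1:3), "not reachable")
})

test_that("active cells sample the higher end of the mossy range", {
  cfg <- defaultCfg
  strip <- smallStrip(cfg, seed = 49)
  go <- golgiConversion(strip, cfg, seed = 50)
  g <- calibrateGain(strip, go, 0.30, cfg, seed = 51, nPerField = 2000L)
  gr <- granuleActivation(strip, go, g, cfg, seed = 52, nPerField = 2000L)
  mossyMean <- mean(normalizeHz(unlist(fieldRates(strip)), cfg))
  expect_gt(mean(unlist(activeRates(gr))), mossyMean)
})

test_that("microfile aggregation pools strips and narrows fractions", {
  cfg <- defaultCfg
  strip <- smallStrip(cfg, seed = 53)
  go <- golgiConversion(strip, cfg, seed = 54)
  gr <- granuleActivation(strip, go, 1.0, cfg, seed = 55,
    nPerField = 1000L)
  # identical strips give identical microfiles
  pf <- microfileAggregate(list(gr, gr), cfg)
  expect_equal(activeFraction(pf), activeFraction(gr))
  expect_equal(lengths(activeRates(pf)), 2L * gr@nActive)
  expect_error(microfileAggregate(list(gr, gr), cfg, weights = 1),
    "one pooling weight")
  # aggregation across independent strips narrows the fraction spread
  strips <- lapply(1:8, function(i) {
    s <- smallStrip(cfg, seed = 60 + i)
    g <- golgiConversion(s, cfg, seed = 70 + i)
    granuleActivation(s, g, 1.0, cfg, seed = 80 + i, nPerField = 1000L)
  })
  pooled <- microfileAggregate(strips, cfg)
  perField <- unlist(lapply(strips, activeFraction))
  expect_lt(sd(activeFraction(pooled)), sd(perField))
  # sqrt(n-strips) oracle for the narrowing, within a factor-of-two band
  expect_lt(sd(activeFraction(pooled)), 2 * sd(perField) / sqrt(8))
})

test_that("the same code is carried by any random sample of active rates", {
  cfg <- defaultCfg
  strip <- smallStrip(cfg, seed = 90)
  go <- golgiConversion(strip, cfg, seed = 91)
  g <- calibrateGain(strip, go, 0.30, cfg, seed = 92, nPerField = 1000L)
  gr <- granuleActivation(strip, go, g, cfg, seed = 93, nPerField = 1000L)
  pool <- unlist(activeRates(gr))
  set.seed(94)
  pick <- sample.int(length(pool), 1000L)
  ks <- suppressWarnings(stats::ks.test(pool[pick[1:500]],
    pool[pick[501:1000]]))
  expect_gt(ks$p.value, 0.01)
})
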