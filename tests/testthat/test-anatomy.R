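test_that("derived anatomical quantities match the model's constants", {
  cfg <- defaultCfg
  expect_identical(fieldsPerNetwork(cfg), 4000L)
  expect_identical(microzonesPerMicrostrip(cfg), 40L)
  expect_equal(duplicationCostPct(cfg), 97, tolerance = 0.001)
  expect_equal(pfPerMicrofile(cfg), 350000)
  expect_equal(pfContactsPerPc(cfg), 175000)
  expect_identical(golgiEnsembleSpanFields(cfg), 5L)
  expect_equal(maxCombinedDcnRate(cfg), 13500)
  expect_gte(sharedPfFraction(cfg, 1L), 95)
})

test_that("derived quantities handle degenerate and arbitrary geometries", {
  expect_identical(
    fieldsPerNetwork(networkConfig(nMicrostripsNominal = 1,
      fieldsPerMicrostrip = 1, microzoneLengthUm = 200)), 1L)
  # direct multiplication oracle
  expect_identical(
    fieldsPerNetwork(networkConfig(nMicrostripsNominal = 7,
      fieldsPerMicrostrip = 13, microzoneLengthUm = 2600)), 91L)
  # one microzone per side when the half-length equals the width
  expect_identical(
    microzonesPerMicrostrip(networkConfig(pfHalfLengthUm = 150)), 2L)
  # floor arithmetic oracle
  expect_identical(
    microzonesPerMicrostrip(networkConfig(pfHalfLengthUm = 1000,
      microzoneWidthUm = 300)), 6L)
  # no duplication when each signal arrives once
  expect_equal(duplicationCostPct(networkConfig(
    terminalsPerClusterMean = 1, branchesPerMfPerMicrostrip = 1)), 0)
  expect_equal(duplicationCostPct(networkConfig(
    terminalsPerClusterMean = 2, branchesPerMfPerMicrostrip = 2)), 75)
  expect_error(duplicationCostPct(networkConfig(
    terminalsPerClusterMean = 0.5, branchesPerMfPerMicrostrip = 1)),
    "at least 1")
  # ensemble span: single cell, single field
  expect_identical(golgiEnsembleSpanFields(defaultCfg, 1L, 1L), 1L)
})

test_that("shared parallel fibre fraction declines linearly to zero", {
  cfg <- defaultCfg
  expect_equal(sharedPfFraction(cfg, 0L), 100)
  expect_equal(sharedPfFraction(cfg, 41L), 0)
  expect_equal(sharedPfFraction(cfg, 60L), 0)
  offs <- 0:45
  vals <- sharedPfFraction(cfg, offs)
  expect_true(all(diff(vals) <= 0))
  expect_error(sharedPfFraction(cfg, -1L), "non-negative")
})

test_that("duplication cost is monotone in both factors and accessors are pure", {
  tpc <- seq(2, 10, 2)
  costT <- vapply(tpc, function(x) duplicationCostPct(networkConfig(
    terminalsPerClusterMean = x)), 1.0)
  costB <- vapply(tpc, function(x) duplicationCostPct(networkConfig(
    branchesPerMfPerMicrostrip = x)), 1.0)
  expect_true(all(diff(costT) > 0))
  expect_true(all(diff(costB) > 0))
  expect_identical(describeNetwork(defaultCfg), describeNetwork(defaultCfg))
})

test_that("configuration validity rejects inconsistent anatomy", {
  expect_error(networkConfig(pfContactFraction = 1.5), "\\[0, 1\\]")
  expect_error(networkConfig(glomerulusGolgiSample = c(12L, 8L)),
    "low <= high")
  expect_error(networkConfig(fieldsPerMicrostrip = 50), "microzoneLengthUm")
  expect_error(networkConfig(minDominantInputs = 5), "granuleDendrites")
  expect_error(networkConfig(inversionKI = 0.2), "kI > kE")
  expect_error(networkConfig(bogusField = 1), "unknown configuration")
  expect_error(networkConfig(1), "named")
})
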