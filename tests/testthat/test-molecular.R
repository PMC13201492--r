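pfCodeFixture <- function(nFiles = 20, af = 0.01, n = 400, seed = 101) {
  set.seed(seed)
  new("ParallelFiberCode",
    activeFraction = rep(af, nFiles),
    rates = replicate(nFiles, 0.7 + 0.06 * stats::rnorm(n),
      simplify = FALSE),
    weights = replicate(nFiles, rep(1, n), simplify = FALSE))
}

test_that("stellate active-input counts follow the regulated fraction", {
  cfg <- defaultCfg
  # at 0.5% active parallel fibres a stellate cell sees single figures
  pf <- pfCodeFixture(af = 0.005)
  st <- stellateInputs(pf, cfg, seed = 102)
  expect_equal(dim(st), c(20, cfg@stellatePerSector))
  # silent code: every cell at the spontaneous floor
  none <- pfCodeFixture(af = 0)
  st0 <- stellateInputs(none, cfg, seed = 103)
  expect_true(all(st0 == cfg@stellateSpontaneous))
  # binomial oracle on the expected active-input count
  kBar <- cfg@stellatePfContacts * 0.005
  expect_lt(kBar, 10)  # "in single figures"
  expect_error(stellateInputs(new("ParallelFiberCode",
    activeFraction = numeric(0), rates = list(), weights = list()), cfg),
    "empty")
})

test_that("constant stellate rates pass through compartments unchanged", {
  cfg <- defaultCfg
  st <- matrix(0.42, nrow = 10, ncol = cfg@stellatePerSector)
  mol <- purkinjeCompartments(st, cfg, seed = 104)
  expect_true(all(abs(mol@compartmentMeans - 0.42) < 1e-12))
  expect_true(all(abs(pcSomaInhibition(mol) - 0.42) < 1e-12))
  expect_equal(pcSomaRate(mol),
    rep(linearInversion(0.42), 10 * cfg@pcPerSector))
  expect_length(mol@sector, 10 * cfg@pcPerSector)
})

test_that("compartment integration narrows the stellate distribution", {
  cfg <- defaultCfg
  pf <- pfCodeFixture(nFiles = 100, af = 0.01, seed = 105)
  st <- stellateInputs(pf, cfg, seed = 106)
  mol <- purkinjeCompartments(st, cfg, seed = 107)
  expect_lt(sd(pcSomaInhibition(mol)), sd(st))
  # each soma is the mean of its compartment means
  expect_equal(pcSomaInhibition(mol), rowMeans(mol@compartmentMeans))
  expect_error(purkinjeCompartments(matrix(numeric(0), 0, 0), cfg),
    "empty")
})

test_that("the linear inversion is decreasing, clamped and validated", {
  expect_equal(linearInversion(0), 1)
  expect_equal(linearInversion(0.5, r0 = 1, kE = 0.5, kI = 1.5), 0.5)
  x <- seq(0, 1, 0.05)
  y <- linearInversion(x, r0 = 0.9, kE = 0.2, kI = 1.9)
  expect_true(all(diff(y) <= 0))
  expect_true(all(y >= 0 & y <= 1))
  expect_error(linearInversion(0.5, kE = 1.5, kI = 1.0), "kI > kE")
  expect_error(linearInversion(0.5, r0 = 0), "r0")
})
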