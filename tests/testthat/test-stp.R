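test_that("the STP sum reduces to identities at its edges", {
  t <- seq(0, 999)
  wave <- 2 + sin(2 * pi * t / 250)
  expect_equal(netInhibitionWave(wave, 0), wave)
  expect_error(netInhibitionWave(wave[1:2], 1), "3 samples")
  expect_error(netInhibitionWave(wave - 2, 1), "strictly positive")
  # identical waves: no shift
  sh0 <- measureTimeShift(wave, wave, 250)
  expect_equal(sh0@shiftMs, 0, tolerance = 1e-6)
  expect_error(measureTimeShift(wave, rep(1, 1000), 250), "flat")
  expect_error(measureTimeShift(wave[1:300], wave[1:300], 250), "2 full")
})

test_that("the derivative of a sine is advanced a quarter wavelength", {
  t <- seq(0, 1999)
  wl <- 400
  wave <- 2 + sin(2 * pi * t / wl)
  deriv <- 2 + cos(2 * pi * t / wl)  # d/dt up to scale, kept positive
  sh <- measureTimeShift(wave, deriv, wl)
  expect_equal(sh@shiftMs, wl / 4, tolerance = 0.01)
  expect_equal(sh@shiftDeg, 90, tolerance = 0.5)
})

test_that("measured shifts match atan(k*w)/w on pure sines", {
  for (wl in c(120, 500, 900)) {
    for (k in c(3, 10, 40)) {
      t <- seq(0, 4 * wl - 1)
      input <- 1 + 0.5 * sin(2 * pi * t / wl)
      output <- netInhibitionWave(input, k)
      sh <- measureTimeShift(input, output, wl)
      expect_equal(sh@shiftMs, analyticStpShiftMs(k, wl),
        tolerance = 0.01 * analyticStpShiftMs(k, wl))
    }
  }
})

test_that("equal rate and STP amplitudes give a 45-degree shift", {
  wl <- 500
  k <- wl / (2 * pi)  # k*w = 1: STP amplitude equals rate amplitude
  t <- seq(0, 4 * wl - 1)
  input <- 2 + sin(2 * pi * t / wl)
  sh <- measureTimeShift(input, netInhibitionWave(input, k), wl)
  expect_equal(sh@shiftDeg, 45, tolerance = 0.2)
})

test_that("the time shift is stable in ms but not as a cycle fraction", {
  sweep <- stpShiftSweep(c(100, 250, 500, 1000), k = 10)
  # nearly fixed in milliseconds across a 10x wavelength range
  expect_lt(diff(range(sweep$shiftMs)) / mean(sweep$shiftMs), 0.15)
  # strongly varying as a percentage of wavelength
  expect_gt(max(sweep$shiftPct) / min(sweep$shiftPct), 3)
  expect_true(all(diff(sweep$shiftPct) < 0))
  # long-wavelength limit: the shift approaches k
  lim <- stpShiftSweep(1e4, k = 10)
  expect_equal(lim$shiftMs, 10, tolerance = 0.02 * 10)
  # stronger STP influence shifts further at fixed wavelength
  k5 <- stpShiftSweep(400, k = 5)$shiftMs
  k20 <- stpShiftSweep(400, k = 20)$shiftMs
  expect_gt(k20, k5)
})
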