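# Anguilliform swimming pipeline: map a fraction of one body wave onto
# the 41 afferent microstrips, run the full network computation, and ask
# whether the DCN output can "read" cycle phase. A full body wave cancels
# in the pooled parallel fibre code (output is phase-invariant); a quarter
# wave survives pooling, so output tracks phase and wavelength.

#' Pooling weights of the afferent strips
#'
#' Uniform by default. When `distalTaperMin < 1` the weight declines
#' linearly from 1 at the central strip to `distalTaperMin` at the most
#' distal strip, reflecting sparser distal parallel fibre synapses.
#'
#' @param cfg a [NetworkConfig-class].
#' @return numeric vector of length `nMicrostrips`.
#' @export
stripPoolingWeights <- function(cfg) {
  n <- cfg@nMicrostrips
  centre <- (n + 1) / 2
  d <- abs(seq_len(n) - centre)
  1 - (1 - cfg@distalTaperMin) * d / max(d)
}

#' Run one instant of the swimming pipeline
#'
#' Builds the commanded sinusoidal input profile, simulates every strip
#' through the granular layer (at the supplied or calibrated gain),
#' aggregates the parallel fibre code, runs the molecular layer, and
#' forms the 50 DCN group rates.
#'
#' @param waveFraction fraction of one body wavelength across the strip
#'   row, in (0, 1].
#' @param phase cycle phase in radians.
#' @param cfg a [NetworkConfig-class].
#' @param seed optional integer seed (locally scoped).
#' @param gain granule inhibition gain; `NULL` calibrates it once at the
#'   reference (constant `meanHz`) condition to `targetFraction`.
#' @param meanHz,ampHz centre and amplitude of the commanded body wave.
#' @param spec template per-strip [RateSpec-class] (spread and bounds).
#' @param targetFraction granule active-fraction target for the swim run
#'   (0.30, the dense code; at sparse targets the dominance threshold
#'   collides with the rate ceiling for strips commanded near 300 Hz).
#' @param nPerField granule cells simulated per field.
#' @return a [SwimSnapshot-class].
#' @export
runSwimSnapshot <- function(waveFraction, phase, cfg = networkConfig(),
                            seed = NULL, gain = NULL, meanHz = 175,
                            ampHz = 125, spec = rateSpec("normal", sd = 25),
                            targetFraction = 0.3,
                            nPerField = cfg@granulePerField) {
  if (waveFraction <= 0 || waveFraction > 1)
    stop("waveFraction must lie in (0, 1]")
  nStrips <- cfg@nMicrostrips
  specs <- sineWaveProfile(nStrips, waveFraction, phase, meanHz, ampHz, spec)
  if (is.null(gain))
    gain <- referenceGain(cfg, seed = stageSeed(seed, 99L), meanHz = meanHz,
      spec = spec, target = targetFraction)
  nMf <- mfPerStrip(cfg)
  outputs <- vector("list", nStrips)
  stripMean <- stripSd <- numeric(nStrips)
  for (i in seq_len(nStrips)) {
    s0 <- stageSeed(seed, 100L + i)
    rates <- drawRates(specs[[i]], nMf, seed = stageSeed(s0, 1L))
    stripMean[i] <- mean(rates)
    stripSd[i] <- stats::sd(rates)
    ms <- deriveFieldRates(rates, cfg, stripIndex = i,
      seed = stageSeed(s0, 2L))
    outputs[[i]] <- simulateStrip(ms, gain, cfg, seed = stageSeed(s0, 3L),
      nPerField = nPerField)$granular
  }
  pf <- microfileAggregate(outputs, cfg, weights = stripPoolingWeights(cfg))
  mol <- simulateMolecularLayer(pf, cfg, seed = stageSeed(seed, 300L))
  dcn <- dcnGroupRates(mol@pcSomaRate, cfg, seed = stageSeed(seed, 301L))
  centreIdx <- (nStrips - 1) / 2
  new("SwimSnapshot",
    phase = as.numeric(phase),
    waveFraction = as.numeric(waveFraction),
    stripMeanHz = stripMean,
    stripSdHz = stripSd,
    dcnOutputs = dcn,
    inputCenterHz = meanHz + ampHz * sin(phase + 2 * pi * waveFraction *
      centreIdx / (nStrips - 1)),
    gain = as.numeric(gain))
}

# Calibrate the network gain once at the reference condition: a strip
# receiving the commanded centre rate with the template spread.
referenceGain <- function(cfg, seed = NULL, meanHz = 175,
                          spec = rateSpec("normal", sd = 25),
                          target = cfg@granuleTargetFraction,
                          nFields = 20L, nPerField = 2000L) {
  s <- spec
  s@mean <- meanHz
  rates <- drawRates(s, mfPerStrip(cfg), seed = stageSeed(seed, 1L))
  ms <- deriveFieldRates(rates, cfg, seed = stageSeed(seed, 2L))
  golgi <- golgiConversion(ms, cfg, seed = stageSeed(seed, 3L))
  as.numeric(calibrateGain(ms, golgi, target, cfg,
    seed = stageSeed(seed, 4L), fields = seq_len(nFields),
    nPerField = nPerField))
}

#' Phase sweep and readability index
#'
#' Runs [runSwimSnapshot()] at `nPhases` equally spaced phases of one
#' cycle (with a single gain calibrated at the reference condition) and
#' quantifies how much of the commanded input modulation survives to the
#' DCN output:
#' `index = range(snapshot mean outputs) / range(normalized commanded
#' centre at the microzone)`. Near 0 for full-wave input (phase is not
#' recoverable), near 1 for quarter-wave input (phase is recoverable).
#'
#' @inheritParams runSwimSnapshot
#' @param nPhases number of phases (>= 4; default 8).
#' @return list with `index`, and a data.frame `sweep` holding `phase`,
#'   `outputMean`, `outputSd`, `inputCenterHz` per phase, plus the `gain`
#'   used.
#' @export
phaseSweep <- function(waveFraction, nPhases = 8, cfg = networkConfig(),
                       seed = NULL, meanHz = 175, ampHz = 125,
                       spec = rateSpec("normal", sd = 25),
                       targetFraction = 0.3,
                       nPerField = cfg@granulePerField) {
  nPhases <- as.integer(nPhases)
  if (nPhases < 4L) stop("need at least 4 phases")
  gain <- referenceGain(cfg, seed = stageSeed(seed, 99L), meanHz = meanHz,
    spec = spec, target = targetFraction)
  phases <- 2 * pi * (seq_len(nPhases) - 1L) / nPhases
  rows <- lapply(seq_along(phases), function(i) {
    sn <- runSwimSnapshot(waveFraction, phases[i], cfg,
      seed = stageSeed(seed, 1000L + i), gain = gain, meanHz = meanHz,
      ampHz = ampHz, spec = spec, targetFraction = targetFraction,
      nPerField = nPerField)
    data.frame(phase = phases[i], outputMean = mean(sn@dcnOutputs),
      outputSd = stats::sd(sn@dcnOutputs),
      inputCenterHz = sn@inputCenterHz)
  })
  sweep <- do.call(rbind, rows)
  inputNorm <- normalizeHz(sweep$inputCenterHz, cfg)
  denom <- diff(range(inputNorm))
  index <- if (denom > 0) diff(range(sweep$outputMean)) / denom else NA_real_
  list(index = index, sweep = sweep, gain = gain)
}
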