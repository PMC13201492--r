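# DCN stage: spike-level Purkinje -> DCN convergence. Irregular spike
# timing with a shared time-varying discharge probability; convergence
# and a short rolling readout window unmask the rate code.

#' Generate a spike raster from a shared discharge probability
#'
#' Every millisecond each of `nAfferents` virtual Purkinje cells spikes
#' independently with probability `rateCurve/1000` (rate in Hz per 1-ms
#' bin). All afferents share the same probability curve -- the
#' synchronized discharge probability of a microzone.
#'
#' @param nAfferents number of afferent cells (> 0).
#' @param rateCurve numeric, expected rate in Hz per bin; each value must
#'   lie in [0, 1000].
#' @param seed optional integer seed (locally scoped).
#' @param binMs bin width in ms (default 1).
#' @return a [SpikeRaster-class].
#' @export
generateRaster <- function(nAfferents, rateCurve, seed = NULL, binMs = 1) {
  nAfferents <- as.integer(nAfferents)
  if (nAfferents <= 0L) stop("nAfferents must be positive")
  if (any(rateCurve < 0) || any(rateCurve > 1000 / binMs))
    stop("rates must lie in [0, ", 1000 / binMs, "] Hz (probability <= 1)")
  tn <- length(rateCurve)
  withSeed(seed, {
    p <- rep(rateCurve * binMs / 1000, each = nAfferents)
    sp <- matrix(as.integer(stats::runif(nAfferents * tn) < p),
      nrow = nAfferents)
    new("SpikeRaster", spikes = sp, probCurve = as.numeric(rateCurve),
      binMs = binMs)
  })
}

#' Converge a raster onto one DCN and smooth the readout
#'
#' Sums spikes over afferents per bin and applies a centred rolling mean
#' of `windowMs` (shrinking at the ends), the DCN's short temporal
#' integration window. `expected` is the per-bin expected count.
#'
#' @param raster a [SpikeRaster-class].
#' @param windowMs rolling window in ms (>= 1; default 2).
#' @return a [DCNTrace-class].
#' @export
convergeAndSmooth <- function(raster, windowMs = 2) {
  if (windowMs < 1) stop("window must be at least 1 ms")
  combined <- as.numeric(colSums(raster@spikes))
  new("DCNTrace",
    combined = combined,
    smoothed = rollingMean(combined, round(windowMs / raster@binMs)),
    expected = nrow(raster@spikes) * raster@probCurve * raster@binMs / 1000,
    windowMs = as.numeric(windowMs))
}

#' Readout reliability versus convergence ratio
#'
#' For each convergence ratio, simulates `nReplicates` independent
#' convergent traces driven by the same probability curve over `cycles`
#' cycles, and returns the mean Pearson correlation over all replicate
#' pairs, for the raw per-ms counts and for the smoothed readout.
#' Reliability rises steeply at low ratios and saturates above the
#' physiological mean (~45).
#'
#' @param ratios integer vector of convergence ratios (e.g. `seq(10, 80,
#'   10)`).
#' @param cycleCurve numeric, one cycle of the expected rate in Hz per ms
#'   (see [sinusoidalRateCurve()]).
#' @param cycles number of cycles to simulate (default 20).
#' @param windowMs smoothing window in ms (default 2).
#' @param nReplicates replicate data sets per ratio (>= 2; default 10).
#' @param seed optional integer seed (locally scoped).
#' @return data.frame with columns `ratio`, `corRaw`, `corSmoothed`.
#' @export
reliabilityCurve <- function(ratios, cycleCurve, cycles = 20, windowMs = 2,
                             nReplicates = 10, seed = NULL) {
  if (nReplicates < 2) stop("need at least 2 replicate data sets per ratio")
  curve <- rep(cycleCurve, cycles)
  withSeed(seed, {
    res <- lapply(ratios, function(r) {
      traces <- lapply(seq_len(nReplicates), function(i)
        convergeAndSmooth(generateRaster(r, curve), windowMs))
      raw <- vapply(traces, function(tr) tr@combined, numeric(length(curve)))
      smo <- vapply(traces, function(tr) tr@smoothed, numeric(length(curve)))
      pairCor <- function(m) {
        cm <- stats::cor(m)
        mean(cm[upper.tri(cm)])
      }
      c(corRaw = pairCor(raw), corSmoothed = pairCor(smo))
    })
    out <- do.call(rbind, res)
    data.frame(ratio = as.integer(ratios), corRaw = out[, "corRaw"],
      corSmoothed = out[, "corSmoothed"])
  })
}

#' Sinusoidal expected-rate curve
#'
#' One cycle of a rate oscillating between `minHz` and `maxHz` (default
#' the Purkinje range 30--300 Hz), sampled at 1 ms.
#'
#' @param wavelengthMs cycle duration in ms.
#' @param minHz,maxHz rate bounds in Hz.
#' @param phase starting phase in radians.
#' @return numeric vector of length `wavelengthMs`.
#' @export
sinusoidalRateCurve <- function(wavelengthMs, minHz = 30, maxHz = 300,
                                phase = 0) {
  t <- seq_len(wavelengthMs) - 1L
  mid <- (minHz + maxHz) / 2
  amp <- (maxHz - minHz) / 2
  mid + amp * sin(phase + 2 * pi * t / wavelengthMs)
}

#' Median relative deviation of a convergent readout
#'
#' `median(|count - expected| / expected)` over bins with positive
#' expectation: the per-ms noise of the readout relative to the coded
#' rate. Falls with the convergence ratio and with smoothing.
#'
#' @param trace a [DCNTrace-class].
#' @param smoothed use the smoothed readout (default TRUE).
#' @return numeric scalar.
#' @export
relativeDeviation <- function(trace, smoothed = TRUE) {
  x <- if (smoothed) trace@smoothed else trace@combined
  ok <- trace@expected > 0
  stats::median(abs(x[ok] - trace@expected[ok]) / trace@expected[ok])
}

#' DCN group rates from Purkinje soma values
#'
#' Each of the `dcnGroupSize` (50) DCNs receives an independent random
#' sample (size uniform in `pcPerDcn`, 30--50, with replacement) of the
#' microzone's Purkinje soma values and fires at the normalized
#' complement of the sample mean (`1 - m`): DCN rates are inversely
#' linearly related to afferent Purkinje rates. Group SD is below the
#' Purkinje population SD (sample-mean narrowing).
#'
#' @param pcSoma numeric, Purkinje soma values on the normalized scale
#'   (typically `pcSomaRate` of a [MolecularOutput-class]).
#' @param cfg a [NetworkConfig-class].
#' @param seed optional integer seed (locally scoped).
#' @return numeric vector of `dcnGroupSize` normalized DCN rates.
#' @export
dcnGroupRates <- function(pcSoma, cfg, seed = NULL) {
  if (!length(pcSoma)) stop("empty Purkinje population")
  withSeed(seed, {
    sz <- drawIntRange(cfg@dcnGroupSize, cfg@pcPerDcn[1], cfg@pcPerDcn[2])
    vapply(sz, function(s)
      1 - mean(pcSoma[sample.int(length(pcSoma), s, replace = TRUE)]),
      1.0)
  })
}
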