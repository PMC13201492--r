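# Shared fixtures and independent oracles for the suite. Oracles
# re-implement the declared sampling schemes directly (no package
# internals) so the implementation is checked against an independent
# path.

defaultCfg <- networkConfig()

# A small strip fixture: real pipeline objects at reduced field count.
smallStrip <- function(cfg = defaultCfg, spec = rateSpec("uniform"),
                       seed = 404) {
  rates <- drawRates(spec, mfPerStrip(cfg), seed = seed)
  deriveFieldRates(rates, cfg, seed = seed + 1L)
}

# Hand-built microstrip with known per-field glomerular populations.
manualStrip <- function(fieldRatesHz, stripRates = sort(unique(
                          unlist(fieldRatesHz)))) {
  ids <- lapply(fieldRatesHz, function(r) match(r, stripRates))
  new("MicrostripInput", stripIndex = 1L, rates = as.numeric(stripRates),
    fieldRates = lapply(fieldRatesHz, as.numeric),
    fieldClusterIds = lapply(ids, as.integer))
}

# Oracle for the Golgi conversion narrowing: simulates the declared
# two-step scheme by brute force on a pooled rate population and returns
# the SDs of each stage.
golgiNarrowingOracle <- function(pool, cfg, nRep = 1e5) {
  nmf <- cfg@mfPerGolgiDendrite
  nd <- cfg@golgiBasalDendrites
  ng3 <- 3L * cfg@golgiPerField
  dend <- colMeans(matrix(sample(pool, nRep * nmf, replace = TRUE),
    nrow = nmf))
  soma <- colMeans(matrix(dend[seq_len((nRep %/% nd) * nd)], nrow = nd))
  sLo <- cfg@glomerulusGolgiSample[1]
  sHi <- cfg@glomerulusGolgiSample[2]
  nG <- 2e4
  glom <- vapply(seq_len(nG), function(i) {
    ens <- soma[sample.int(length(soma), ng3)]
    mean(ens[sample.int(ng3, sample(sLo:sHi, 1L), replace = TRUE)])
  }, 1.0)
  c(dend = stats::sd(dend), soma = stats::sd(soma), glom = stats::sd(glom))
}

# Exact granule activation probability and expected firing rate for one
# field by enumeration of all dendrite combinations (distinct mossy
# fibres), at a given gain. `rates`/`inh` are per-glomerulus, `ids` maps
# glomeruli to mossy fibres.
granuleEnumOracle <- function(rates, inh, ids, gain, minDom = 3L) {
  m <- length(rates)
  combs <- utils::combn(m, 4L)
  keep <- apply(combs, 2L, function(ix) length(unique(ids[ix])) == 4L)
  combs <- combs[, keep, drop = FALSE]
  dom <- rates > gain * inh
  nDom <- colSums(matrix(dom[combs], nrow = 4L))
  fire <- nDom >= minDom
  rateSum <- colSums(matrix((rates * dom)[combs], nrow = 4L))
  list(pFire = mean(fire),
    meanRate = if (any(fire)) mean(rateSum[fire] / nDom[fire]) else NaN)
}

# Least-squares sinusoid fit R^2 for a phase-indexed response.
sineFitR2 <- function(phase, y) {
  fit <- stats::lm(y ~ sin(phase) + cos(phase))
  summary(fit)$r.squared
}
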