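# Named experiment pipelines with tabular outputs: each reproduces one of
# the model's simulated demonstrations and writes per-stage CSV tables
# plus a JSON run manifest (config snapshot + seed + summaries), so any
# run is reproducible from its manifest alone.

#' Run a named experiment and write its tables
#'
#' Experiments: `describe` (derived anatomical quantities), `golgi`
#' (ensemble conversion narrowing along one strip), `regulation` (active
#' fraction at the dense and sparse targets), `tracking` (pooled granule
#' mean vs mossy mean), `microzone` (full network to Purkinje/DCN
#' synchrony), `convergence` (reliability vs Purkinje->DCN ratio),
#' `swim` (full- and quarter-wave phase sweeps), `stp` (time shift vs
#' wavelength).
#'
#' @param name experiment name.
#' @param cfg a [NetworkConfig-class], or a path to a YAML/JSON config.
#' @param seed integer seed for the run.
#' @param outDir output directory (created if needed).
#' @param ... experiment-specific overrides: `nPerField`, `ratios`,
#'   `cycles`, `nReplicates`, `nPhases`, `wavelengthsMs`, `k`,
#'   `inputMeansHz`.
#' @return invisibly, the manifest list (also written as
#'   `manifest.json`).
#' @export
runExperiment <- function(name, cfg = networkConfig(), seed = 1L,
                          outDir = ".", ...) {
  if (is.character(cfg)) cfg <- readNetworkConfig(cfg)
  known <- c("describe", "golgi", "regulation", "tracking", "microzone",
    "convergence", "swim", "stp")
  if (!name %in% known)
    stop("unknown experiment '", name, "'; choose one of: ",
      paste(known, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fn <- get(paste0("experiment_", name), mode = "function")
  res <- fn(cfg, as.integer(seed), outDir, ...)
  manifest <- list(
    experiment = name,
    seed = as.integer(seed),
    config = configAsList(cfg),
    summaries = res$summaries,
    files = res$files
  )
  mpath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(c(manifest, list(manifestPath = mpath)))
}

writeTable <- function(df, outDir, file) {
  path <- file.path(outDir, file)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

experiment_describe <- function(cfg, seed, outDir) {
  d <- describeNetwork(cfg)
  path <- file.path(outDir, "derived_quantities.json")
  jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  list(summaries = d, files = path)
}

experiment_golgi <- function(cfg, seed, outDir,
                             spec = rateSpec("uniform")) {
  rates <- drawRates(spec, mfPerStrip(cfg), seed = stageSeed(seed, 1L))
  ms <- deriveFieldRates(rates, cfg, seed = stageSeed(seed, 2L))
  go <- golgiConversion(ms, cfg, seed = stageSeed(seed, 3L))
  df <- data.frame(
    field = seq_along(ms@fieldRates),
    mossyMeanHz = vapply(ms@fieldRates, mean, 1.0),
    mossySdHz = vapply(ms@fieldRates, stats::sd, 1.0),
    golgiMean = vapply(go@golgiRates, mean, 1.0),
    golgiSd = vapply(go@golgiRates, stats::sd, 1.0),
    glomMean = vapply(go@glomInhibition, mean, 1.0),
    glomSd = vapply(go@glomInhibition, stats::sd, 1.0)
  )
  f <- writeTable(df, outDir, "golgi_conversion.csv")
  list(summaries = list(
    mossyMeanHz = mean(rates),
    glomMeanHz = denormalizeHz(mean(unlist(go@glomInhibition)), cfg),
    sdNarrowing = stats::sd(unlist(go@glomInhibition)) /
      stats::sd(normalizeHz(unlist(ms@fieldRates), cfg))
  ), files = f)
}

experiment_regulation <- function(cfg, seed, outDir,
                                  nPerField = cfg@granulePerField,
                                  targets = c(dense = 0.30, sparse = 0.01)) {
  rates <- drawRates(rateSpec("uniform"), mfPerStrip(cfg),
    seed = stageSeed(seed, 1L))
  ms <- deriveFieldRates(rates, cfg, seed = stageSeed(seed, 2L))
  go <- golgiConversion(ms, cfg, seed = stageSeed(seed, 3L))
  rows <- list()
  summ <- list()
  for (nm in names(targets)) {
    g <- calibrateGain(ms, go, targets[[nm]], cfg,
      seed = stageSeed(seed, 4L), nPerField = min(nPerField, 2000L))
    gr <- granuleActivation(ms, go, g, cfg, seed = stageSeed(seed, 5L),
      nPerField = nPerField)
    rows[[nm]] <- data.frame(regime = nm, field = seq_along(gr@nActive),
      activePct = 100 * activeFraction(gr))
    summ[[paste0(nm, "Gain")]] <- as.numeric(g)
    summ[[paste0(nm, "MeanActivePct")]] <- 100 * mean(activeFraction(gr))
  }
  f <- writeTable(do.call(rbind, rows), outDir, "active_fraction.csv")
  list(summaries = summ, files = f)
}

experiment_tracking <- function(cfg, seed, outDir,
                                inputMeansHz = seq(100, 250, length.out = 6),
                                nPerField = cfg@granulePerField) {
  base <- rateSpec("normal", mean = 175, sd = 25)
  refRates <- drawRates(base, mfPerStrip(cfg), seed = stageSeed(seed, 1L))
  refMs <- deriveFieldRates(refRates, cfg, seed = stageSeed(seed, 2L))
  refGo <- golgiConversion(refMs, cfg, seed = stageSeed(seed, 3L))
  gain <- calibrateGain(refMs, refGo, cfg@granuleTargetFraction, cfg,
    seed = stageSeed(seed, 4L), nPerField = min(nPerField, 2000L))
  rows <- lapply(seq_along(inputMeansHz), function(i) {
    s <- base
    s@mean <- inputMeansHz[i]
    r <- drawRates(s, mfPerStrip(cfg), seed = stageSeed(seed, 10L + i))
    m <- deriveFieldRates(r, cfg, seed = stageSeed(seed, 30L + i))
    g <- golgiConversion(m, cfg, seed = stageSeed(seed, 50L + i))
    gr <- granuleActivation(m, g, gain, cfg, seed = stageSeed(seed, 70L + i),
      nPerField = nPerField)
    pooled <- unlist(gr@activeRates)
    data.frame(inputMeanHz = inputMeansHz[i], mossyMeanHz = mean(r),
      granuleMean = mean(pooled), granuleSd = stats::sd(pooled),
      activePct = 100 * mean(activeFraction(gr)))
  })
  df <- do.call(rbind, rows)
  fit <- stats::lm(granuleMean ~ mossyMeanHz, data = df)
  f <- writeTable(df, outDir, "linear_tracking.csv")
  list(summaries = list(slopePerHz = unname(stats::coef(fit)[2]),
    r2 = summary(fit)$r.squared), files = f)
}

experiment_microzone <- function(cfg, seed, outDir,
                                 nPerField = cfg@granulePerField) {
  net <- simulateNetwork(cfg, seed = seed, spec = rateSpec("uniform"),
    nPerField = nPerField)
  mol <- net$molecular
  df <- data.frame(
    pc = seq_along(mol@pcSomaRate), sector = mol@sector,
    somaInhibition = mol@pcSomaInhibition, somaRate = mol@pcSomaRate)
  f1 <- writeTable(df, outDir, "purkinje_soma.csv")
  f2 <- writeTable(data.frame(dcn = seq_along(net$dcn), rate = net$dcn),
    outDir, "dcn_group.csv")
  list(summaries = list(
    stellateSd = stats::sd(mol@stellateRates),
    pcSomaSd = stats::sd(mol@pcSomaInhibition),
    dcnSd = stats::sd(net$dcn),
    dcnMean = mean(net$dcn)
  ), files = c(f1, f2))
}

experiment_convergence <- function(cfg, seed, outDir,
                                   ratios = seq(10, 80, 10),
                                   cycles = 20, nReplicates = 10,
                                   wavelengthMs = 500, windowMs = 2) {
  curve <- sinusoidalRateCurve(wavelengthMs, cfg@pcRateMinHz,
    cfg@pcRateMaxHz)
  df <- reliabilityCurve(ratios, curve, cycles = cycles,
    windowMs = windowMs, nReplicates = nReplicates, seed = seed)
  f <- writeTable(df, outDir, "reliability.csv")
  list(summaries = list(
    corSmoothedAtMeanRatio = df$corSmoothed[which.min(abs(df$ratio - 45))],
    corRawAtMeanRatio = df$corRaw[which.min(abs(df$ratio - 45))]
  ), files = f)
}

experiment_swim <- function(cfg, seed, outDir, nPhases = 8,
                            nPerField = cfg@granulePerField) {
  full <- phaseSweep(1, nPhases, cfg, seed = stageSeed(seed, 1L),
    nPerField = nPerField)
  quarter <- phaseSweep(0.25, nPhases, cfg, seed = stageSeed(seed, 2L),
    nPerField = nPerField)
  full$sweep$waveFraction <- 1
  quarter$sweep$waveFraction <- 0.25
  f <- writeTable(rbind(full$sweep, quarter$sweep), outDir,
    "phase_sweep.csv")
  list(summaries = list(fullWaveIndex = full$index,
    quarterWaveIndex = quarter$index), files = f)
}

experiment_stp <- function(cfg, seed, outDir,
                           wavelengthsMs = c(100, 200, 500, 1000),
                           k = cfg@stpGainMs) {
  df <- stpShiftSweep(wavelengthsMs, k = k)
  f <- writeTable(df, outDir, "stp_shift.csv")
  list(summaries = list(k = k,
    shiftMsRange = range(df$shiftMs)), files = f)
}

#' Simulate one full network at a single instant
#'
#' Uniform machinery used by the microzone experiment and tests: all
#' strips draw from the same `spec`, the gain is calibrated to
#' `granuleTargetFraction`, and the chain runs through to the DCN group.
#'
#' @param cfg a [NetworkConfig-class].
#' @param seed optional integer seed.
#' @param spec per-strip input [RateSpec-class].
#' @param nPerField granule cells simulated per field.
#' @param gain optional pre-calibrated gain.
#' @return list with `pf` ([ParallelFiberCode-class]), `molecular`
#'   ([MolecularOutput-class]), `dcn` (numeric), `gain`.
#' @export
simulateNetwork <- function(cfg = networkConfig(), seed = NULL,
                            spec = rateSpec("uniform"),
                            nPerField = cfg@granulePerField, gain = NULL) {
  nStrips <- cfg@nMicrostrips
  if (is.null(gain))
    gain <- referenceGain(cfg, seed = stageSeed(seed, 99L),
      meanHz = mean(c(spec@low, spec@high)), spec = spec)
  outputs <- vector("list", nStrips)
  for (i in seq_len(nStrips)) {
    s0 <- stageSeed(seed, 100L + i)
    rates <- drawRates(spec, mfPerStrip(cfg), seed = stageSeed(s0, 1L))
    ms <- deriveFieldRates(rates, cfg, stripIndex = i,
      seed = stageSeed(s0, 2L))
    outputs[[i]] <- simulateStrip(ms, gain, cfg, seed = stageSeed(s0, 3L),
      nPerField = nPerField)$granular
  }
  pf <- microfileAggregate(outputs, cfg, weights = stripPoolingWeights(cfg))
  mol <- simulateMolecularLayer(pf, cfg, seed = stageSeed(seed, 300L))
  dcn <- dcnGroupRates(mol@pcSomaRate, cfg, seed = stageSeed(seed, 301L))
  list(pf = pf, molecular = mol, dcn = dcn, gain = gain)
}
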