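# Granular layer: Golgi ensemble conversion, glomerular spillover
# inhibition, granule activation, gain calibration, microfile aggregation.
# All computation is on the normalized [0, 1] rate scale; successive
# random-sampling stages narrow the distribution (central limit theorem)
# while keeping means linearly coupled.

#' Two-step Golgi ensemble conversion
#'
#' Step 1 (mossy fibre -> Golgi): in each field, each of
#' `golgiPerField` (10) Golgi cells holds `golgiBasalDendrites` (5)
#' dendritic charge states, each the mean of `mfPerGolgiDendrite` (4)
#' glomerular rates sampled from the local field; the somatic rate is the
#' mean of the cell's five dendritic states.
#'
#' Step 2 (Golgi -> glomerulus): every glomerulus of a field receives
#' spillover inhibition equal to the mean of a random sample (size 8--12)
#' of somatic rates from the 3-field ensemble centred on the field (30
#' cells; truncated to a 2-field ensemble at the strip ends). Sampling is
#' with replacement. On the normalized scale the expected inhibition
#' equals the mossy fibre population mean, so inhibition linearly tracks
#' mossy rates while each stage narrows the spread.
#'
#' @param strip a [MicrostripInput-class].
#' @param cfg a [NetworkConfig-class].
#' @param seed optional integer seed (locally scoped).
#' @return a [GolgiOutput-class] (values on the normalized scale).
#' @export
golgiConversion <- function(strip, cfg, seed = NULL) {
  fr <- strip@fieldRates
  nf <- length(fr)
  if (nf < 3L)
    stop("need at least 3 fields for the Golgi ensemble conversion")
  fieldNorm <- lapply(fr, normalizeHz, cfg = cfg)
  ng <- cfg@golgiPerField
  nd <- cfg@golgiBasalDendrites
  nmf <- cfg@mfPerGolgiDendrite
  withSeed(seed, {
    lens <- lengths(fieldNorm)
    perField <- ng * nd * nmf
    all <- unlist(fieldNorm, use.names = FALSE)
    offs <- c(0L, cumsum(lens))[seq_len(nf)]
    # step 1: dendritic samples for every field at once
    pick <- floor(stats::runif(nf * perField) *
      rep(lens, each = perField)) + 1L
    pick <- pick + rep(offs, each = perField)
    dendMean <- colMeans(matrix(all[pick], nrow = nmf))
    dendByField <- matrix(dendMean, nrow = ng * nd)
    somaByField <- matrix(colMeans(matrix(dendMean, nrow = nd)), nrow = ng)
    # step 2: per-glomerulus ensemble samples
    glom <- vector("list", nf)
    sLo <- cfg@glomerulusGolgiSample[1]
    sHi <- cfg@glomerulusGolgiSample[2]
    for (f in seq_len(nf)) {
      ens <- as.numeric(somaByField[, max(1L, f - 1L):min(nf, f + 1L)])
      m <- lens[f]
      sz <- drawIntRange(m, sLo, sHi)
      tot <- sum(sz)
      draws <- ens[floor(stats::runif(tot) * length(ens)) + 1L]
      grp <- rep.int(seq_len(m), sz)
      glom[[f]] <- as.numeric(rowsum(draws, grp) / sz)
    }
    new("GolgiOutput",
      dendriticMeans = lapply(seq_len(nf), function(f) dendByField[, f]),
      golgiRates = lapply(seq_len(nf), function(f) somaByField[, f]),
      glomInhibition = glom)
  })
}

#' Granule cell activation
#'
#' Each simulated granule cell samples `granuleDendrites` (4) glomeruli of
#' its field, enforced to carry signals of distinct mossy fibres. A mossy
#' input is dominant when its normalized rate exceeds `gain` times the
#' inhibition of its own glomerulus. A cell fires iff it has at least
#' `minDominantInputs` (3) dominant inputs, at a rate equal to the mean of
#' its dominant input rates.
#'
#' @param strip a [MicrostripInput-class].
#' @param inh a [GolgiOutput-class] for the same strip.
#' @param gain positive inhibition gain (see [calibrateGain()]).
#' @param cfg a [NetworkConfig-class].
#' @param seed optional integer seed (locally scoped).
#' @param nPerField granule cells simulated per field (defaults to
#'   `granulePerField`).
#' @param fields integer indices of the fields to simulate (default all).
#' @return a [GranularOutput-class].
#' @export
granuleActivation <- function(strip, inh, gain, cfg, seed = NULL,
                              nPerField = cfg@granulePerField,
                              fields = seq_along(strip@fieldRates)) {
  if (gain < 0) stop("gain must be non-negative")
  withSeed(seed, {
    sam <- granuleSamples(strip, inh, cfg, nPerField, fields)
    granuleDecide(sam, gain, cfg, nPerField)
  })
}

# Draw the dendritic sampling structure once: per cell, granuleDendrites
# glomerulus picks with distinct source mossy fibres; returns normalized
# excitation and matching glomerular inhibition matrices (cells x
# dendrites). Vectorized across all fields of the strip.
granuleSamples <- function(strip, inh, cfg, nPerField, fields) {
  nd <- cfg@granuleDendrites
  lens <- lengths(strip@fieldRates[fields])
  if (any(lens < nd))
    stop("some fields have fewer glomeruli than granule dendrites")
  rates <- normalizeHz(unlist(strip@fieldRates[fields], use.names = FALSE),
    cfg)
  ids <- unlist(strip@fieldClusterIds[fields], use.names = FALSE)
  gin <- unlist(inh@glomInhibition[fields], use.names = FALSE)
  offs <- rep.int(c(0L, cumsum(lens))[seq_along(fields)],
    rep(nPerField, length(fields)))
  lenRow <- rep.int(lens, rep(nPerField, length(fields)))
  n <- length(lenRow)
  idx <- matrix(floor(stats::runif(n * nd) * lenRow) + 1L, nrow = n)
  hasDup <- function(sub) {
    cid <- matrix(ids[sub + offs[attr(sub, "rows")]], ncol = nd)
    dup <- rep(FALSE, nrow(cid))
    for (a in seq_len(nd - 1L)) for (b in seq(a + 1L, nd))
      dup <- dup | cid[, a] == cid[, b]
    dup
  }
  # redraw rows whose picks repeat a mossy fibre until all are distinct
  bad <- seq_len(n)
  repeat {
    sub <- idx[bad, , drop = FALSE]
    attr(sub, "rows") <- bad
    dup <- hasDup(sub)
    bad <- bad[dup]
    if (!length(bad)) break
    idx[bad, ] <- floor(stats::runif(length(bad) * nd) * lenRow[bad]) + 1L
  }
  gIdx <- idx + offs
  list(exc = matrix(rates[gIdx], nrow = n),
    inh = matrix(gin[gIdx], nrow = n), fields = fields)
}

# Threshold the sampled structure at a given gain.
granuleDecide <- function(sam, gain, cfg, nPerField) {
  dom <- sam$exc > gain * sam$inh
  ndom <- rowSums(dom)
  fire <- ndom >= cfg@minDominantInputs
  rate <- rowSums(sam$exc * dom)[fire] / ndom[fire]
  fieldOf <- rep(seq_along(sam$fields), each = nPerField)[fire]
  act <- split(rate, factor(fieldOf, levels = seq_along(sam$fields)))
  new("GranularOutput",
    nActive = as.integer(lengths(act)),
    activeRates = lapply(act, as.numeric),
    nSimulated = as.integer(nPerField),
    gain = as.numeric(gain))
}

#' Calibrate the Golgi coupling gain to an active-fraction target
#'
#' Bisection on the gain until the mean active granule fraction across the
#' simulated fields is within `tol` (relative) of `targetFraction`. The
#' dendritic sampling structure is drawn once and reused for every gain
#' evaluated (common random numbers), which makes the empirical active
#' fraction exactly non-increasing in the gain; the search asserts this
#' monotonicity and errors with diagnostics if the target cannot be
#' bracketed.
#'
#' @param strip a [MicrostripInput-class].
#' @param inh a [GolgiOutput-class] for the same strip.
#' @param targetFraction target mean active fraction, in (0, 1).
#' @param cfg a [NetworkConfig-class].
#' @param seed optional integer seed (locally scoped).
#' @param fields field indices used for calibration (default all; a
#'   subset speeds the search at slight precision cost).
#' @param nPerField granule cells simulated per field during calibration.
#' @param tol relative tolerance on the achieved fraction (0.02).
#' @param maxIter maximum bisection steps.
#' @return the calibrated gain (numeric scalar) with attribute
#'   `achievedFraction`.
#' @export
calibrateGain <- function(strip, inh, targetFraction, cfg, seed = NULL,
                          fields = seq_along(strip@fieldRates),
                          nPerField = cfg@granulePerField, tol = 0.02,
                          maxIter = 60L) {
  if (targetFraction <= 0 || targetFraction >= 1)
    stop("targetFraction must lie in (0, 1)")
  withSeed(seed, {
    sam <- granuleSamples(strip, inh, cfg, nPerField, fields)
    frac <- function(g) {
      dom <- sam$exc > g * sam$inh
      mean(rowSums(dom) >= cfg@minDominantInputs)
    }
    lo <- 0
    hi <- 2
    fLo <- frac(lo)
    if (fLo < targetFraction)
      stop(sprintf(paste("target fraction %.3g is not reachable: even with",
        "no inhibition only %.3g of cells receive %d distinct inputs"),
        targetFraction, fLo, cfg@minDominantInputs))
    while (frac(hi) > targetFraction) {
      hi <- hi * 2
      if (hi > 1e6) stop("active fraction does not fall below target: ",
        "empirical curve failed to bracket (hi > 1e6)")
    }
    fPrev <- fLo
    gPrev <- lo
    for (it in seq_len(maxIter)) {
      mid <- (lo + hi) / 2
      fMid <- frac(mid)
      if (mid >= gPrev && fMid > fPrev + 1e-12)
        stop(sprintf(paste("active fraction increased from %.4g to %.4g as",
          "gain rose from %.4g to %.4g; empirical curve is not monotone"),
          fPrev, fMid, gPrev, mid))
      gPrev <- mid
      fPrev <- fMid
      if (abs(fMid - targetFraction) <= tol * targetFraction) break
      if (fMid > targetFraction) lo <- mid else hi <- mid
    }
    structure((lo + hi) / 2, achievedFraction = fPrev)
  })
}

#' Aggregate granule output into the per-microfile parallel fibre code
#'
#' Microfile j pools field j of every simulated strip. Each strip's
#' contribution can be weighted (see `weights`; used by the swimming
#' pipeline's distal taper, default uniform). Returns the active fraction
#' and pooled rate population per microfile -- the parallel fibre code
#' seen by the overlying microzone.
#'
#' @param outputs list of [GranularOutput-class], one per strip, all
#'   simulated with the same calibrated gain and field count.
#' @param cfg a [NetworkConfig-class].
#' @param weights optional numeric vector, one pooling weight per strip.
#' @return a [ParallelFiberCode-class].
#' @export
microfileAggregate <- function(outputs, cfg, weights = NULL) {
  ns <- length(outputs)
  if (!ns) stop("no strip outputs supplied")
  nf <- unique(vapply(outputs, function(o) length(o@nActive), 1L))
  if (length(nf) != 1L)
    stop("strips were simulated with differing field counts")
  if (is.null(weights)) weights <- rep(1, ns)
  if (length(weights) != ns)
    stop("need one pooling weight per strip")
  af <- numeric(nf)
  rates <- weightsOut <- vector("list", nf)
  for (j in seq_len(nf)) {
    fracs <- vapply(outputs, function(o) o@nActive[j] / o@nSimulated, 1.0)
    af[j] <- wmean(fracs, weights)
    rates[[j]] <- unlist(lapply(outputs, function(o) o@activeRates[[j]]),
      use.names = FALSE)
    weightsOut[[j]] <- rep.int(weights,
      vapply(outputs, function(o) o@nActive[j], 1L))
  }
  new("ParallelFiberCode", activeFraction = af, rates = rates,
    weights = weightsOut)
}

#' Simulate the granular layer of one strip end to end
#'
#' Convenience wrapper: Golgi conversion then granule activation, with an
#' externally calibrated gain.
#'
#' @inheritParams granuleActivation
#' @return list with elements `golgi` ([GolgiOutput-class]) and
#'   `granular` ([GranularOutput-class]).
#' @export
simulateStrip <- function(strip, gain, cfg, seed = NULL,
                          nPerField = cfg@granulePerField) {
  golgi <- golgiConversion(strip, cfg, seed = stageSeed(seed, 1L))
  gran <- granuleActivation(strip, golgi, gain, cfg,
    seed = stageSeed(seed, 2L), nPerField = nPerField)
  list(golgi = golgi, granular = gran)
}
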