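#' Derive per-field glomerular rate populations from a strip population
#'
#' Implements mossy fibre terminal clustering. Each field independently
#' samples `mfPerField` (180) mossy fibres from the strip population,
#' with replacement; each sampled fibre contributes a terminal cluster
#' whose size is drawn uniformly from `clusterSizeRange` (7 or 8 copies
#' of the same rate). Clusters are as large as a field and straddle field
#' boundaries, so only part of each cluster falls inside the field: each
#' copy is retained independently with a per-cluster probability drawn
#' uniformly around [clusterInFieldFraction()] (+/-
#' `straddleMaxFraction`); the remaining copies lie in adjacent fields,
#' which is represented implicitly because neighbouring fields draw their
#' own samples, straddling clusters included, from the same strip
#' population. A field's glomerular population is therefore about
#' `terminalsPerField` (~700) values carried by ~180 distinct mossy
#' fibres. Copies add no new rate values.
#'
#' @param stripRates numeric, strip mossy fibre rate population in Hz
#'   (e.g. from [drawRates()] with `n = mfPerStrip(cfg)`).
#' @param cfg a [NetworkConfig-class].
#' @param stripIndex integer label for the strip.
#' @param seed optional integer seed (locally scoped).
#' @return a [MicrostripInput-class].
#' @export
deriveFieldRates <- function(stripRates, cfg, stripIndex = 1L, seed = NULL) {
  if (!length(stripRates)) stop("strip rate population is empty")
  nf <- cfg@fieldsPerMicrostrip
  nc <- cfg@mfPerField
  pIn <- clusterInFieldFraction(cfg)
  w <- min(cfg@straddleMaxFraction, pIn, 1 - pIn)
  withSeed(seed, {
    total <- nf * nc
    # one mossy fibre draw per cluster, fields concatenated
    mfIdx <- sample.int(length(stripRates), total, replace = TRUE)
    csize <- drawIntRange(total, cfg@clusterSizeRange[1],
      cfg@clusterSizeRange[2])
    keep <- stats::rbinom(total, csize, stats::runif(total, pIn - w, pIn + w))
    fieldOf <- rep.int(rep(seq_len(nf), each = nc), keep)
    clustOf <- rep.int(mfIdx, keep)
    splitIdx <- split(clustOf, factor(fieldOf, levels = seq_len(nf)))
    new("MicrostripInput",
      stripIndex = as.integer(stripIndex),
      rates = as.numeric(stripRates),
      fieldRates = lapply(splitIdx, function(id) as.numeric(stripRates[id])),
      fieldClusterIds = lapply(splitIdx, as.integer))
  })
}
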