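#' Derived anatomical quantities
#'
#' Pure functions of a [NetworkConfig-class] computing the model's derived
#' geometric and cost quantities. Where the anatomy is conventionally
#' tallied with the round strip count (40 rather than the 41 afferent
#' strips including the centre one), the accessor says so.
#'
#' @param cfg a [NetworkConfig-class].
#' @name anatomy
NULL

#' Fields per network
#'
#' Total fields feeding one microzone, using the nominal strip count
#' (40 x 100 = 4,000 by default).
#'
#' @inheritParams anatomy
#' @return integer count.
#' @export
fieldsPerNetwork <- function(cfg) {
  as.integer(cfg@nMicrostripsNominal) * as.integer(cfg@fieldsPerMicrostrip)
}

#' Microzones reached by one microstrip's parallel fibres
#'
#' Parallel fibres run half their length each way, so a strip reaches
#' `2 * floor(pfHalfLength / microzoneWidth)` microzones (40 by default,
#' 20 each side).
#'
#' @inheritParams anatomy
#' @return integer count.
#' @export
microzonesPerMicrostrip <- function(cfg) {
  if (cfg@microzoneWidthUm <= 0) stop("microzone width must be positive")
  2L * as.integer(floor(cfg@pfHalfLengthUm / cfg@microzoneWidthUm))
}

#' Granule-cell cost of signal duplication
#'
#' Each mossy fibre signal reaches granule cells in many copies (terminal
#' clusters of ~7.5 terminals, ~4.5 terminal branches per strip). The
#' fraction of the granule population attributable to receiving duplicate
#' copies is `100 * (1 - 1 / (terminalsPerCluster * branches))`, about 97%
#' at the default anatomy.
#'
#' @inheritParams anatomy
#' @return percentage in [0, 100).
#' @export
duplicationCostPct <- function(cfg) {
  copies <- cfg@terminalsPerClusterMean * cfg@branchesPerMfPerMicrostrip
  if (copies < 1) stop("terminals x branches must be at least 1")
  100 * (1 - 1 / copies)
}

#' Parallel fibres shared by two microzones
#'
#' Fraction (%) of parallel fibres received in common by two microzones
#' `offsetStrips` strips apart: a linear decline from 100% at offset 0,
#' reaching 0 when the offset equals the afferent strip count (41).
#' Immediate neighbours share > 95%.
#'
#' @inheritParams anatomy
#' @param offsetStrips non-negative integer separation in strips.
#' @return percentage in [0, 100].
#' @export
sharedPfFraction <- function(cfg, offsetStrips) {
  if (any(offsetStrips < 0)) stop("offsetStrips must be non-negative")
  s <- as.numeric(cfg@nMicrostrips)
  100 * pmax(0, s - offsetStrips) / s
}

#' Parallel fibres entering a microzone from one microfile
#'
#' `granulePerField x nominal strip count` (8,750 x 40 = 350,000).
#'
#' @inheritParams anatomy
#' @return count.
#' @export
pfPerMicrofile <- function(cfg) {
  as.numeric(cfg@granulePerField) * cfg@nMicrostripsNominal
}

#' Parallel fibre contacts on one Purkinje cell
#'
#' Half of the ~350,000 passing fibres make contact (175,000).
#'
#' @inheritParams anatomy
#' @return count.
#' @export
pfContactsPerPc <- function(cfg) {
  cfg@pfPassingPc * cfg@pfContactFraction
}

#' Combined sagittal span of a Golgi ensemble
#'
#' Golgi cells in a sagittal row of `rowFields` fields each have an axonal
#' span of `cellSpanFields` fields centred on their own; the union spans
#' `rowFields + cellSpanFields - 1` fields (5 for the default 3-field
#' ensemble).
#'
#' @inheritParams anatomy
#' @param rowFields fields in the ensemble row (3).
#' @param cellSpanFields per-cell axonal span in fields (3).
#' @return integer count.
#' @export
golgiEnsembleSpanFields <- function(cfg, rowFields = 3L, cellSpanFields = 3L) {
  stopifnot(rowFields >= 1L, cellSpanFields >= 1L)
  as.integer(rowFields) + as.integer(cellSpanFields) - 1L
}

#' Maximum combined spike rate converging on one DCN
#'
#' Mean convergence ratio times the Purkinje rate ceiling
#' (45 x 300 = 13,500 Hz).
#'
#' @inheritParams anatomy
#' @return rate in Hz.
#' @export
maxCombinedDcnRate <- function(cfg) {
  as.numeric(cfg@pcPerDcnMean) * cfg@pcRateMaxHz
}

#' Expected in-field fraction of a terminal cluster
#'
#' Terminal clusters are about the size of a field and straddle field
#' boundaries, so only part of each cluster's terminals lies inside the
#' field. The expected in-field fraction reconciles the three anatomical
#' constants: `terminalsPerField / (mfPerField x terminalsPerClusterMean)`
#' (700 / (180 x 7.5) ~ 0.52).
#'
#' @inheritParams anatomy
#' @return fraction in (0, 1].
#' @export
clusterInFieldFraction <- function(cfg) {
  f <- cfg@terminalsPerField /
    (cfg@mfPerField * cfg@terminalsPerClusterMean)
  if (f <= 0 || f > 1)
    stop("inconsistent anatomy: in-field cluster fraction outside (0, 1]")
  f
}

#' Distinct mossy fibre population of one microstrip
#'
#' `fields x mfPerField / branchesPerMf` (100 x 180 / 4.5 = 4,000): the
#' number of distinct mossy fibres whose terminal branches tile the strip.
#'
#' @inheritParams anatomy
#' @return integer count.
#' @export
mfPerStrip <- function(cfg) {
  as.integer(round(cfg@fieldsPerMicrostrip * cfg@mfPerField /
    cfg@branchesPerMfPerMicrostrip))
}

#' All derived quantities as a named list
#'
#' @inheritParams anatomy
#' @return named list of the derived quantities, suitable for JSON output.
#' @examples
#' describeNetwork(networkConfig())
#' @export
describeNetwork <- function(cfg) {
  list(
    fields_per_network = fieldsPerNetwork(cfg),
    microzones_per_microstrip = microzonesPerMicrostrip(cfg),
    duplication_cost_pct = duplicationCostPct(cfg),
    shared_pf_pct_offset1 = sharedPfFraction(cfg, 1L),
    pf_per_microfile = pfPerMicrofile(cfg),
    pf_contacts_per_pc = pfContactsPerPc(cfg),
    functional_pf_contacts_per_pc =
      pfContactsPerPc(cfg) * (1 - cfg@silentSynapseFraction),
    golgi_ensemble_span_fields = golgiEnsembleSpanFields(cfg),
    max_combined_dcn_rate_hz = maxCombinedDcnRate(cfg),
    cluster_in_field_fraction = clusterInFieldFraction(cfg),
    mf_per_strip = mfPerStrip(cfg)
  )
}
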