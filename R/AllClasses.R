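#' @import methods
NULL

#' Anatomical and model configuration of one cerebellar network
#'
#' A `NetworkConfig` holds every anatomical constant of the model -- cell
#' counts, convergence/divergence ratios, physical dimensions and rate
#' ranges -- together with the few model coefficients (granule activation
#' gain target, Purkinje inversion coefficients, STP derivative gain).
#' All derived geometric quantities (see [describeNetwork()]) are pure
#' functions of this object, and no downstream stage hard-codes a constant.
#'
#' Two microstrip-count conventions coexist in the anatomy: `nMicrostrips`
#' (41) counts the afferent strips feeding one microzone, 20 each side plus
#' the strip directly beneath; `nMicrostripsNominal` (40) is the round
#' count used for nominal per-network tallies (4,000 fields, 350,000
#' parallel fibres per microfile). Accessors document which they apply.
#'
#' @slot nMicrostrips integer, afferent microstrips per network (41).
#' @slot nMicrostripsNominal integer, nominal strip count for derived
#'   per-network tallies (40).
#' @slot fieldsPerMicrostrip integer, fields per microstrip (100).
#' @slot mfPerField integer, mossy fibres contributing terminals to a
#'   field (180).
#' @slot terminalsPerField integer, glomeruli per field (700).
#' @slot terminalsPerClusterMean numeric, mean terminals per cluster (7.5).
#' @slot clusterSizeRange integer(2), admissible cluster sizes (7--8).
#' @slot branchesPerMfPerMicrostrip numeric, terminal branches per mossy
#'   fibre per microstrip (4.5).
#' @slot straddleMaxFraction numeric, maximum fraction of a cluster's
#'   terminals spilling across a field boundary (0.3).
#' @slot golgiPerField integer (10).
#' @slot golgiBasalDendrites integer (5).
#' @slot mfPerGolgiDendrite integer (4).
#' @slot glomerulusGolgiSample integer(2), per-glomerulus Golgi sample size
#'   range (8--12).
#' @slot granulePerField integer (8750).
#' @slot granuleDendrites integer (4; admissible 3--5).
#' @slot minDominantInputs integer, minimum dominant inputs to fire (3).
#' @slot pfHalfLengthUm numeric, parallel fibre half-length (3000).
#' @slot microzoneLengthUm numeric (20000).
#' @slot microzoneWidthUm numeric (150).
#' @slot fieldSagittalUm numeric (200).
#' @slot fieldMediolateralUm numeric (150).
#' @slot sectorsPerMicrozone integer (100).
#' @slot pcPerSector integer (4).
#' @slot stellatePerSector integer (80).
#' @slot stellatePerPcInner integer, inner stellate cells per sector
#'   afferent to one Purkinje cell (16, 8 per side).
#' @slot stellateSagittalSpanSectors integer, odd sagittal span (in
#'   sectors) of the stellate axonal territory; a Purkinje dendritic
#'   compartment samples inner stellate cells of its own sector and
#'   neighbours within this span (5, i.e. +/- 2 sectors ~ 450 um).
#' @slot pfPassingPc numeric, parallel fibres crossing one Purkinje
#'   dendritic territory (350000).
#' @slot pfContactFraction numeric, fraction making contact (0.5).
#' @slot silentSynapseFraction numeric, fraction of pf--PC synapses that
#'   are silent (0.825).
#' @slot stellatePfContacts integer, parallel fibre contacts per stellate
#'   cell (1000).
#' @slot stellateSpontaneous numeric, normalized output of a stellate cell
#'   with no active input (0.1).
#' @slot pcCompartments integer, Purkinje dendritic compartments (16).
#' @slot compartmentStellateSample integer(2), stellate sample size range
#'   per compartment (8--12).
#' @slot dcnGroupSize integer, DCNs per output group (50).
#' @slot pcPerDcn integer(2), Purkinje cells converging on one DCN
#'   (30--50).
#' @slot pcPerDcnMean integer (45).
#' @slot boutonsPerPc integer(2), boutons per Purkinje axon on a DCN
#'   (24--36; not modelled as separate release sites).
#' @slot mossyRateMinHz,mossyRateMaxHz numeric, physiological mossy fibre
#'   rate range (50--300 Hz), also the normalization bounds.
#' @slot pcRateMinHz,pcRateMaxHz numeric, Purkinje rate range used at the
#'   spike-generation stage (30--300 Hz).
#' @slot granuleTargetFraction numeric, default target for the regulated
#'   active granule fraction (0.01, the sparse code).
#' @slot inversionR0,inversionKE,inversionKI numeric, coefficients of the
#'   Purkinje excitation/inhibition linear inversion (1.0, 0.5, 1.5).
#' @slot distalTaperMin numeric in (0, 1]; weight given to the most distal
#'   afferent strip when pooling parallel fibre signals. 1 (default) pools
#'   uniformly; 0.5 applies a linear taper so distal strips contribute
#'   half as strongly.
#' @slot stpGainMs numeric, derivative gain k of the Purkinje-to-DCN
#'   short-term-plasticity model, in ms (10).
#'
#' @seealso [networkConfig()], [describeNetwork()], [readNetworkConfig()]
#' @export
setClass("NetworkConfig",
  representation(
    nMicrostrips = "integer",
    nMicrostripsNominal = "integer",
    fieldsPerMicrostrip = "integer",
    mfPerField = "integer",
    terminalsPerField = "integer",
    terminalsPerClusterMean = "numeric",
    clusterSizeRange = "integer",
    branchesPerMfPerMicrostrip = "numeric",
    straddleMaxFraction = "numeric",
    golgiPerField = "integer",
    golgiBasalDendrites = "integer",
    mfPerGolgiDendrite = "integer",
    glomerulusGolgiSample = "integer",
    granulePerField = "integer",
    granuleDendrites = "integer",
    minDominantInputs = "integer",
    pfHalfLengthUm = "numeric",
    microzoneLengthUm = "numeric",
    microzoneWidthUm = "numeric",
    fieldSagittalUm = "numeric",
    fieldMediolateralUm = "numeric",
    sectorsPerMicrozone = "integer",
    pcPerSector = "integer",
    stellatePerSector = "integer",
    stellatePerPcInner = "integer",
    stellateSagittalSpanSectors = "integer",
    pfPassingPc = "numeric",
    pfContactFraction = "numeric",
    silentSynapseFraction = "numeric",
    stellatePfContacts = "integer",
    stellateSpontaneous = "numeric",
    pcCompartments = "integer",
    compartmentStellateSample = "integer",
    dcnGroupSize = "integer",
    pcPerDcn = "integer",
    pcPerDcnMean = "integer",
    boutonsPerPc = "integer",
    mossyRateMinHz = "numeric",
    mossyRateMaxHz = "numeric",
    pcRateMinHz = "numeric",
    pcRateMaxHz = "numeric",
    granuleTargetFraction = "numeric",
    inversionR0 = "numeric",
    inversionKE = "numeric",
    inversionKI = "numeric",
    distalTaperMin = "numeric",
    stpGainMs = "numeric"
  ),
  prototype(
    nMicrostrips = 41L,
    nMicrostripsNominal = 40L,
    fieldsPerMicrostrip = 100L,
    mfPerField = 180L,
    terminalsPerField = 700L,
    terminalsPerClusterMean = 7.5,
    clusterSizeRange = c(7L, 8L),
    branchesPerMfPerMicrostrip = 4.5,
    straddleMaxFraction = 0.3,
    golgiPerField = 10L,
    golgiBasalDendrites = 5L,
    mfPerGolgiDendrite = 4L,
    glomerulusGolgiSample = c(8L, 12L),
    granulePerField = 8750L,
    granuleDendrites = 4L,
    minDominantInputs = 3L,
    pfHalfLengthUm = 3000,
    microzoneLengthUm = 20000,
    microzoneWidthUm = 150,
    fieldSagittalUm = 200,
    fieldMediolateralUm = 150,
    sectorsPerMicrozone = 100L,
    pcPerSector = 4L,
    stellatePerSector = 80L,
    stellatePerPcInner = 16L,
    stellateSagittalSpanSectors = 5L,
    pfPassingPc = 350000,
    pfContactFraction = 0.5,
    silentSynapseFraction = 0.825,
    stellatePfContacts = 1000L,
    stellateSpontaneous = 0.1,
    pcCompartments = 16L,
    compartmentStellateSample = c(8L, 12L),
    dcnGroupSize = 50L,
    pcPerDcn = c(30L, 50L),
    pcPerDcnMean = 45L,
    boutonsPerPc = c(24L, 36L),
    mossyRateMinHz = 50,
    mossyRateMaxHz = 300,
    pcRateMinHz = 30,
    pcRateMaxHz = 300,
    granuleTargetFraction = 0.01,
    inversionR0 = 1.0,
    inversionKE = 0.5,
    inversionKI = 1.5,
    distalTaperMin = 1.0,
    stpGainMs = 10
  ),
  validity = function(object) {
    msg <- character()
    counts <- c("nMicrostrips", "nMicrostripsNominal", "fieldsPerMicrostrip",
      "mfPerField", "terminalsPerField", "golgiPerField",
      "golgiBasalDendrites", "mfPerGolgiDendrite", "granulePerField",
      "granuleDendrites", "minDominantInputs", "sectorsPerMicrozone",
      "pcPerSector", "stellatePerSector", "stellatePerPcInner",
      "stellateSagittalSpanSectors",
      "stellatePfContacts", "pcCompartments", "dcnGroupSize", "pcPerDcnMean")
    for (nm in counts) {
      v <- slot(object, nm)
      if (length(v) != 1L || is.na(v) || v <= 0L)
        msg <- c(msg, sprintf("'%s' must be a single positive count", nm))
    }
    fracs <- c("pfContactFraction", "silentSynapseFraction",
      "straddleMaxFraction", "granuleTargetFraction")
    for (nm in fracs) {
      v <- slot(object, nm)
      if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
        msg <- c(msg, sprintf("'%s' must lie in [0, 1]", nm))
    }
    ranges <- c("clusterSizeRange", "glomerulusGolgiSample",
      "compartmentStellateSample", "pcPerDcn", "boutonsPerPc")
    for (nm in ranges) {
      v <- slot(object, nm)
      if (length(v) != 2L || any(is.na(v)) || v[1] > v[2] || v[1] <= 0L)
        msg <- c(msg, sprintf("'%s' must be a positive range low <= high", nm))
    }
    pos <- c("terminalsPerClusterMean", "branchesPerMfPerMicrostrip",
      "pfHalfLengthUm", "microzoneLengthUm", "microzoneWidthUm",
      "fieldSagittalUm", "fieldMediolateralUm", "pfPassingPc", "stpGainMs")
    for (nm in pos) {
      v <- slot(object, nm)
      if (length(v) != 1L || is.na(v) || v <= 0)
        msg <- c(msg, sprintf("'%s' must be a single positive number", nm))
    }
    if (object@mossyRateMinHz < 0 ||
        object@mossyRateMinHz >= object@mossyRateMaxHz)
      msg <- c(msg, "mossy rate range must satisfy 0 <= min < max")
    if (object@pcRateMinHz < 0 || object@pcRateMinHz >= object@pcRateMaxHz)
      msg <- c(msg, "Purkinje rate range must satisfy 0 <= min < max")
    if (object@fieldsPerMicrostrip * object@fieldSagittalUm !=
        object@microzoneLengthUm)
      msg <- c(msg, paste("fieldsPerMicrostrip x fieldSagittalUm must equal",
        "microzoneLengthUm (default geometry consistency)"))
    if (object@minDominantInputs > object@granuleDendrites)
      msg <- c(msg, "minDominantInputs must not exceed granuleDendrites")
    if (object@inversionKI <= object@inversionKE || object@inversionKE < 0)
      msg <- c(msg, "inversion coefficients must satisfy kI > kE >= 0")
    if (object@inversionR0 <= 0 || object@inversionR0 > 1)
      msg <- c(msg, "inversionR0 must lie in (0, 1]")
    if (object@distalTaperMin <= 0 || object@distalTaperMin > 1)
      msg <- c(msg, "distalTaperMin must lie in (0, 1]")
    if (object@stellateSpontaneous < 0 || object@stellateSpontaneous > 1)
      msg <- c(msg, "stellateSpontaneous must lie in [0, 1]")
    if (object@stellateSagittalSpanSectors %% 2L != 1L)
      msg <- c(msg, "stellateSagittalSpanSectors must be odd (centred span)")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a network configuration
#'
#' Returns the default anatomical configuration, with any named slot
#' overridden. Integer-valued slots accept plain numerics and are coerced.
#'
#' @param ... named slot overrides, e.g. `granuleTargetFraction = 0.3`.
#' @return A validated [NetworkConfig-class] object.
#' @examples
#' cfg <- networkConfig()
#' sparse <- networkConfig(granuleTargetFraction = 0.01)
#' @export
networkConfig <- function(...) {
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(names(args) == "")))
    stop("all arguments to networkConfig() must be named")
  proto <- getSlots("NetworkConfig")
  bad <- setdiff(names(args), names(proto))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  for (nm in names(args)) {
    if (proto[[nm]] == "integer") args[[nm]] <- as.integer(args[[nm]])
    else args[[nm]] <- as.numeric(args[[nm]])
  }
  do.call(new, c(list("NetworkConfig"), args))
}

#' Parameterized mossy fibre rate distribution
#'
#' Describes one family of firing-rate distributions from which mossy
#' fibre inputs are drawn. All draws are clipped to `[low, high]` Hz.
#' Families: `"constant"` (all rates equal `mean`), `"uniform"` (on
#' `[low, high]`), `"normal"` (`mean`, `sd`, clipped), `"bimodal"` (equal
#' mixture of two normals centred at `peaks` with common `sd`, clipped)
#' and `"discontinuous"` (uniform on `[low, high]` with the open interval
#' `gap` excised).
#'
#' @slot family character, one of the five families above.
#' @slot mean,sd numeric, location/spread in Hz (families that use them).
#' @slot low,high numeric, hard rate bounds in Hz.
#' @slot peaks numeric(2), bimodal peak locations in Hz.
#' @slot gap numeric(2), excluded interval for the discontinuous family.
#' @seealso [rateSpec()], [drawRates()]
#' @export
setClass("RateSpec",
  representation(family = "character", mean = "numeric", sd = "numeric",
    low = "numeric", high = "numeric", peaks = "numeric", gap = "numeric"),
  prototype(family = "uniform", mean = 175, sd = 25, low = 50, high = 300,
    peaks = c(100, 250), gap = c(125, 225)),
  validity = function(object) {
    fams <- c("constant", "uniform", "normal", "bimodal", "discontinuous")
    msg <- character()
    if (length(object@family) != 1L || !object@family %in% fams)
      msg <- c(msg, paste("family must be one of:",
        paste(fams, collapse = ", ")))
    if (object@low < 0 || object@low >= object@high)
      msg <- c(msg, "bounds must satisfy 0 <= low < high")
    if (length(object@gap) != 2L || object@gap[1] > object@gap[2])
      msg <- c(msg, "gap must be an interval low <= high")
    if (length(object@peaks) != 2L)
      msg <- c(msg, "peaks must have length 2")
    if (object@family %in% c("normal", "bimodal") &&
        (length(object@sd) != 1L || object@sd < 0))
      msg <- c(msg, "sd must be a single non-negative number")
    if (length(msg)) msg else TRUE
  }
)

#' Mossy fibre input to one microstrip, resolved to fields
#'
#' Holds the strip-level population of mossy fibre firing rates and, for
#' each field, the copies-added glomerular rate population derived from it
#' by terminal-cluster sampling (one value per glomerulus, in Hz).
#' `fieldClusterIds` records, for every glomerular value, the index of the
#' source mossy fibre draw in `rates`, so that copies of the same signal
#' can be recognised downstream (granule dendrites must contact distinct
#' mossy fibres).
#'
#' @slot stripIndex integer position of the strip in the network row.
#' @slot rates numeric, strip mossy fibre rate population (Hz).
#' @slot fieldRates list of numeric vectors, one per field (Hz).
#' @slot fieldClusterIds list of integer vectors parallel to `fieldRates`.
#' @export
setClass("MicrostripInput",
  representation(stripIndex = "integer", rates = "numeric",
    fieldRates = "list", fieldClusterIds = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@fieldRates) != length(object@fieldClusterIds))
      msg <- c(msg, "fieldRates and fieldClusterIds lengths differ")
    else {
      same <- mapply(function(r, id) length(r) == length(id),
        object@fieldRates, object@fieldClusterIds)
      if (!all(same))
        msg <- c(msg, "each field's rates and cluster ids must align")
    }
    if (!length(object@rates))
      msg <- c(msg, "strip rate population is empty")
    if (length(msg)) msg else TRUE
  }
)

#' Output of the two-step Golgi ensemble conversion
#'
#' Per field: the 50 dendritic sample means (10 cells x 5 dendrites), the
#' 10 somatic Golgi rates, and the per-glomerulus inhibition strengths
#' obtained by sampling the 3-field ensemble. All values are on the
#' normalized [0, 1] scale mapped from the mossy fibre rate range.
#'
#' @slot dendriticMeans list of numeric vectors (one per field).
#' @slot golgiRates list of numeric vectors (one per field).
#' @slot glomInhibition list of numeric vectors, one value per glomerulus
#'   of the field.
#' @export
setClass("GolgiOutput",
  representation(dendriticMeans = "list", golgiRates = "list",
    glomInhibition = "list"),
  validity = function(object) {
    n <- length(object@golgiRates)
    if (length(object@dendriticMeans) != n ||
        length(object@glomInhibition) != n)
      return("per-field lists must have equal length")
    TRUE
  }
)

#' Granule layer output for one microstrip
#'
#' Per field: the number of granule cells meeting the conditions to fire
#' and their firing rates (normalized scale, each the mean of that cell's
#' dominant mossy fibre inputs). `nSimulated` is the number of granule
#' cells simulated per field and `gain` the Golgi coupling gain in force.
#'
#' @slot nActive integer vector, active cells per field.
#' @slot activeRates list of numeric vectors, one per field.
#' @slot nSimulated integer, granule cells simulated per field.
#' @slot gain numeric, inhibition gain applied.
#' @export
setClass("GranularOutput",
  representation(nActive = "integer", activeRates = "list",
    nSimulated = "integer", gain = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nActive) != length(object@activeRates))
      msg <- c(msg, "nActive and activeRates lengths differ")
    if (any(object@nActive < 0L) || any(object@nActive > object@nSimulated))
      msg <- c(msg, "nActive must lie in [0, nSimulated]")
    if (any(lengths(object@activeRates) != object@nActive))
      msg <- c(msg, "activeRates lengths must equal nActive")
    if (length(msg)) msg else TRUE
  }
)

#' Parallel fibre code per microfile
#'
#' Aggregates the granule output of all afferent strips by microfile
#' (field j of every strip). `rates` are the pooled active granule rates
#' (normalized), `weights` the per-rate pooling weights (uniform unless a
#' distal taper is configured), and `activeFraction` the weighted active
#' fraction per microfile.
#'
#' @slot activeFraction numeric vector, one value per microfile.
#' @slot rates list of numeric vectors, one per microfile.
#' @slot weights list of numeric vectors parallel to `rates`.
#' @export
setClass("ParallelFiberCode",
  representation(activeFraction = "numeric", rates = "list",
    weights = "list"),
  validity = function(object) {
    msg <- character()
    if (length(object@rates) != length(object@activeFraction) ||
        length(object@weights) != length(object@rates))
      msg <- c(msg, "per-microfile slots must have equal length")
    else if (any(lengths(object@weights) != lengths(object@rates)))
      msg <- c(msg, "weights must align with rates")
    if (any(object@activeFraction < 0 | object@activeFraction > 1))
      msg <- c(msg, "active fractions must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' Molecular layer output for one microzone
#'
#' @slot stellateRates matrix, sectors x stellate cells per sector
#'   (normalized rates).
#' @slot compartmentMeans matrix, Purkinje cells x dendritic compartments.
#' @slot pcSomaInhibition numeric, per-Purkinje mean of compartment means.
#' @slot pcSomaRate numeric, per-Purkinje firing rate after the
#'   excitation/inhibition linear inversion.
#' @slot sector integer, sector index of each Purkinje cell.
#' @export
setClass("MolecularOutput",
  representation(stellateRates = "matrix", compartmentMeans = "matrix",
    pcSomaInhibition = "numeric", pcSomaRate = "numeric",
    sector = "integer"),
  validity = function(object) {
    n <- length(object@pcSomaInhibition)
    if (length(object@pcSomaRate) != n || length(object@sector) != n ||
        nrow(object@compartmentMeans) != n)
      return("per-Purkinje slots must align")
    TRUE
  }
)

#' Millisecond-binned spike raster with a shared discharge probability
#'
#' `spikes` is an `nAfferents x T` 0/1 matrix; each column t is one 1-ms
#' bin in which every afferent spikes independently with probability
#' `probCurve[t] / 1000` (rate in Hz to per-ms probability).
#'
#' @slot spikes integer matrix of 0/1 indicators.
#' @slot probCurve numeric, expected firing rate per bin (Hz).
#' @slot binMs numeric, bin width in ms (1).
#' @export
setClass("SpikeRaster",
  representation(spikes = "matrix", probCurve = "numeric", binMs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@spikes) != length(object@probCurve))
      msg <- c(msg, "probCurve length must equal the number of bins")
    if (!all(object@spikes %in% c(0L, 1L)))
      msg <- c(msg, "spikes must be 0/1")
    if (any(object@probCurve < 0) || any(object@probCurve > 1000 / object@binMs))
      msg <- c(msg, "rates must lie in [0, 1000/binMs] Hz")
    if (length(msg)) msg else TRUE
  }
)

#' Convergent DCN input trace
#'
#' @slot combined numeric, per-bin spike count summed over afferents.
#' @slot smoothed numeric, centred rolling mean of `combined` (window
#'   shrinks at the ends).
#' @slot expected numeric, per-bin expected count
#'   (`nAfferents * probCurve / 1000`).
#' @slot windowMs numeric, rolling window in ms.
#' @export
setClass("DCNTrace",
  representation(combined = "numeric", smoothed = "numeric",
    expected = "numeric", windowMs = "numeric"),
  validity = function(object) {
    n <- length(object@combined)
    if (length(object@smoothed) != n || length(object@expected) != n)
      return("trace components must have equal length")
    TRUE
  }
)

#' Measured phase shift of a summed rate + STP wave
#'
#' @slot wavelengthMs numeric, wavelength of the underlying cycle (ms).
#' @slot shiftDeg numeric, phase advance in degrees.
#' @slot shiftPct numeric, advance as a percentage of wavelength.
#' @slot shiftMs numeric, advance in ms.
#' @export
setClass("StpShift",
  representation(wavelengthMs = "numeric", shiftDeg = "numeric",
    shiftPct = "numeric", shiftMs = "numeric"),
  validity = function(object) {
    if (object@wavelengthMs <= 0) return("wavelengthMs must be positive")
    TRUE
  }
)

#' One instant of the swimming pipeline
#'
#' Captures a snapshot of a network reading part of a body wave: the
#' commanded per-strip input statistics, the 50 normalized DCN outputs,
#' and the input centre commanded at the microzone position.
#'
#' @slot phase numeric, cycle phase in radians.
#' @slot waveFraction numeric, fraction of one body wavelength spanned by
#'   the strip row.
#' @slot stripMeanHz,stripSdHz numeric, realised input mean/SD per strip.
#' @slot dcnOutputs numeric, normalized firing rates of the DCN group.
#' @slot inputCenterHz numeric, commanded input centre at the microzone.
#' @slot gain numeric, granule gain used for the run.
#' @export
setClass("SwimSnapshot",
  representation(phase = "numeric", waveFraction = "numeric",
    stripMeanHz = "numeric", stripSdHz = "numeric", dcnOutputs = "numeric",
    inputCenterHz = "numeric", gain = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@stripMeanHz) != length(object@stripSdHz))
      msg <- c(msg, "per-strip statistics must align")
    if (object@waveFraction <= 0 || object@waveFraction > 1)
      msg <- c(msg, "waveFraction must lie in (0, 1]")
    if (any(object@dcnOutputs < 0 | object@dcnOutputs > 1))
      msg <- c(msg, "DCN outputs must be on the normalized [0, 1] scale")
    if (length(msg)) msg else TRUE
  }
)
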