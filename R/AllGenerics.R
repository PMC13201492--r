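#' Accessor generics
#'
#' Small accessor generics for the simulator's S4 containers, so user code
#' never reaches into slots.
#'
#' @param object an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("activeFraction", function(object) standardGeneric("activeFraction"))

#' @rdname accessors
#' @export
setGeneric("activeRates", function(object) standardGeneric("activeRates"))

#' @rdname accessors
#' @export
setGeneric("dcnOutputs", function(object) standardGeneric("dcnOutputs"))

#' @rdname accessors
#' @export
setGeneric("spikes", function(object) standardGeneric("spikes"))

#' @rdname accessors
#' @export
setGeneric("probCurve", function(object) standardGeneric("probCurve"))

#' @rdname accessors
#' @export
setGeneric("fieldRates", function(object) standardGeneric("fieldRates"))

#' @rdname accessors
#' @export
setGeneric("glomInhibition", function(object) standardGeneric("glomInhibition"))

#' @rdname accessors
#' @export
setGeneric("pcSomaRate", function(object) standardGeneric("pcSomaRate"))

#' @rdname accessors
#' @export
setGeneric("pcSomaInhibition",
  function(object) standardGeneric("pcSomaInhibition"))

#' @rdname accessors
#' @export
setGeneric("stellateRates", function(object) standardGeneric("stellateRates"))

#' Per-field active fraction of a granular layer result
#' @param object a [GranularOutput-class].
#' @return numeric vector, `nActive / nSimulated` per field.
#' @export
setMethod("activeFraction", "GranularOutput",
  function(object) object@nActive / object@nSimulated)

#' @rdname accessors
#' @export
setMethod("activeFraction", "ParallelFiberCode",
  function(object) object@activeFraction)

#' @rdname accessors
#' @export
setMethod("activeRates", "GranularOutput", function(object) object@activeRates)

#' @rdname accessors
#' @export
setMethod("activeRates", "ParallelFiberCode", function(object) object@rates)

#' @rdname accessors
#' @export
setMethod("dcnOutputs", "SwimSnapshot", function(object) object@dcnOutputs)

#' @rdname accessors
#' @export
setMethod("spikes", "SpikeRaster", function(object) object@spikes)

#' @rdname accessors
#' @export
setMethod("probCurve", "SpikeRaster", function(object) object@probCurve)

#' @rdname accessors
#' @export
setMethod("fieldRates", "MicrostripInput", function(object) object@fieldRates)

#' @rdname accessors
#' @export
setMethod("glomInhibition", "GolgiOutput",
  function(object) object@glomInhibition)

#' @rdname accessors
#' @export
setMethod("pcSomaRate", "MolecularOutput", function(object) object@pcSomaRate)

#' @rdname accessors
#' @export
setMethod("pcSomaInhibition", "MolecularOutput",
  function(object) object@pcSomaInhibition)

#' @rdname accessors
#' @export
setMethod("stellateRates", "MolecularOutput",
  function(object) object@stellateRates)

setMethod("show", "NetworkConfig", function(object) {
  cat("NetworkConfig:", object@nMicrostrips, "microstrips x",
    object@fieldsPerMicrostrip, "fields;",
    object@granulePerField, "granule cells/field;",
    object@dcnGroupSize, "DCNs/group\n")
  cat("  mossy rate range:", object@mossyRateMinHz, "-",
    object@mossyRateMaxHz, "Hz; granule target fraction:",
    object@granuleTargetFraction, "\n")
  invisible(NULL)
})

setMethod("show", "RateSpec", function(object) {
  cat("RateSpec(", object@family, ") on [", object@low, ",", object@high,
    "] Hz\n")
  invisible(NULL)
})

setMethod("show", "MicrostripInput", function(object) {
  cat("MicrostripInput: strip", object@stripIndex, "-",
    length(object@rates), "mossy fibres,",
    length(object@fieldRates), "fields, mean",
    round(mean(object@rates), 1), "Hz\n")
  invisible(NULL)
})

setMethod("show", "GranularOutput", function(object) {
  af <- activeFraction(object)
  cat("GranularOutput:", length(object@nActive), "fields;",
    "mean active fraction", signif(mean(af), 3),
    "(gain", signif(object@gain, 4), ")\n")
  invisible(NULL)
})

setMethod("show", "ParallelFiberCode", function(object) {
  cat("ParallelFiberCode:", length(object@rates), "microfiles;",
    "mean active fraction", signif(mean(object@activeFraction), 3), "\n")
  invisible(NULL)
})

setMethod("show", "MolecularOutput", function(object) {
  cat("MolecularOutput:", length(object@pcSomaRate), "Purkinje cells in",
    length(unique(object@sector)), "sectors; soma rate mean",
    signif(mean(object@pcSomaRate), 3), "SD",
    signif(stats::sd(object@pcSomaRate), 3), "\n")
  invisible(NULL)
})

setMethod("show", "SpikeRaster", function(object) {
  cat("SpikeRaster:", nrow(object@spikes), "afferents x",
    ncol(object@spikes), "ms;", sum(object@spikes), "spikes\n")
  invisible(NULL)
})

setMethod("show", "DCNTrace", function(object) {
  cat("DCNTrace:", length(object@combined), "ms; total spikes",
    sum(object@combined), "; window", object@windowMs, "ms\n")
  invisible(NULL)
})

setMethod("show", "StpShift", function(object) {
  cat(sprintf("StpShift: %.2f deg = %.2f%% = %.2f ms (wavelength %g ms)\n",
    object@shiftDeg, object@shiftPct, object@shiftMs, object@wavelengthMs))
  invisible(NULL)
})

setMethod("show", "SwimSnapshot", function(object) {
  cat(sprintf(
    "SwimSnapshot: wave fraction %.2f, phase %.2f rad; DCN mean %.3f SD %.4f\n",
    object@waveFraction, object@phase, mean(object@dcnOutputs),
    stats::sd(object@dcnOutputs)))
  invisible(NULL)
})
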