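#' @name accessors
#' @title Accessors for grclfp objects
#' @description Small accessor generics: sampling step (`sampleInterval`),
#'   trace values (`traceValues`), stimulus onset (`stimulusOnset`),
#'   spike times (`spikeTimes`) and recovered connectivity weights
#'   (`recoveredWeights`).
#' @param x an object.
#' @return `sampleInterval`: ms; `traceValues`: numeric vector (uV for LFP
#'   objects); `stimulusOnset`: ms; `spikeTimes`: ms; `recoveredWeights`:
#'   numeric length-4.
NULL

#' @rdname accessors
#' @export
setGeneric("sampleInterval", function(x) standardGeneric("sampleInterval"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("stimulusOnset", function(x) standardGeneric("stimulusOnset"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("recoveredWeights", function(x) standardGeneric("recoveredWeights"))

#' @rdname accessors
setMethod("sampleInterval", "LfpTrace", function(x) x@dt)
#' @rdname accessors
setMethod("sampleInterval", "Kernel", function(x) x@dt)
#' @rdname accessors
setMethod("sampleInterval", "CompartmentCurrents", function(x) x@dt)
#' @rdname accessors
setMethod("traceValues", "LfpTrace", function(x) x@trace)
#' @rdname accessors
setMethod("traceValues", "Kernel", function(x) x@trace)
#' @rdname accessors
setMethod("stimulusOnset", "LfpTrace", function(x) x@onset_ms)
#' @rdname accessors
setMethod("stimulusOnset", "Kernel", function(x) x@onset_ms)
#' @rdname accessors
setMethod("spikeTimes", "CompartmentCurrents", function(x) x@spikes)
#' @rdname accessors
setMethod("recoveredWeights", "BssResult", function(x) x@weights)

#' Transmembrane current matrix
#' @param x a [CompartmentCurrents-class] object.
#' @return matrix (time step x compartment), nA, outward positive.
#' @export
membraneCurrents <- function(x) {
  stopifnot(is(x, "CompartmentCurrents"))
  x@im
}

#' Somatic voltage trace
#' @param x a [CompartmentCurrents-class] object.
#' @return numeric vector, mV.
#' @export
somaticVoltage <- function(x) {
  stopifnot(is(x, "CompartmentCurrents"))
  x@v_soma
}

setMethod("show", "CellModel", function(object) {
  cp <- object@compartments
  cat("CellModel:", nrow(cp), "compartments (",
      sum(cp$group == "dendrite"), "dendritic,",
      sum(cp$group == "soma"), "soma,",
      sum(cp$group == "hillock"), "hillock,",
      sum(cp$group == "axon"), "axon )\n")
  cat("  IE level:", object@channels$ie_level,
      sprintf("(C_on x%.3g, O_on x%.3g)\n",
              object@channels$con_scale, object@channels$oon_scale))
  if (!is.null(object@protocol)) {
    pr <- object@protocol
    cat(sprintf("  synapses: %d mossy fiber, %d inhibitory (delay %g ms), p = %g\n",
                pr@n_mf, pr@n_goc, pr@goc_delay_ms, object@state@p))
  } else cat("  synapses: none attached\n")
  invisible(object)
})

setMethod("show", "LfpTrace", function(object) {
  cat(sprintf("LfpTrace: %d samples, dt = %g ms (%.1f ms), onset %g ms\n",
              length(object@trace), object@dt,
              length(object@trace) * object@dt, object@onset_ms))
  cat(sprintf("  range [%.3g, %.3g] uV\n",
              min(object@trace), max(object@trace)))
  invisible(object)
})

setMethod("show", "Kernel", function(object) {
  cat(sprintf("Kernel (n_mf = %d, n_goc = %d): %d samples, dt = %g ms, view %s\n",
              object@combo[1], object@combo[2], length(object@trace),
              object@dt, object@electrode@view))
  invisible(object)
})

setMethod("show", "KernelSet", function(object) {
  cat("KernelSet with", length(object@kernels), "kernels:\n")
  print(object@combos)
  invisible(object)
})

setMethod("show", "BssResult", function(object) {
  cat("BssResult\n  recovered weights (n_mf 1..4):",
      paste(sprintf("%.1f%%", 100 * object@weights), collapse = " "), "\n")
  cat(sprintf("  cross-validation MSE: %.4g%%%s\n", object@mse,
              if (object@tie) " (tie between assignments)" else ""))
  if (!object@reliable)
    cat("  WARNING: components look Gaussian; separation may be unreliable\n")
  invisible(object)
})

setMethod("show", "PlasticityState", function(object) {
  cat(sprintf("PlasticityState: p = %g, IE %s\n", object@p, object@ie_level))
  invisible(object)
})
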