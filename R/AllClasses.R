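#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib grclfp, .registration = TRUE
NULL

#' Extracellular medium
#'
#' Purely resistive, homogeneous extracellular medium. Resistivity is stored
#' in Ohm*cm; the constructor [medium()] also accepts the field-potential
#' literature's "MOhm/cm" convention (the resistance per unit length of a
#' 1 cm^2 column, numerically 1e6 Ohm*cm per unit).
#'
#' @slot resistivity numeric, Ohm*cm.
#' @export
setClass("Medium", representation(resistivity = "numeric"))

setValidity("Medium", function(object) {
  if (length(object@resistivity) != 1 || !is.finite(object@resistivity) ||
      object@resistivity <= 0)
    return("resistivity must be a single positive number")
  TRUE
})

#' Recording electrode
#'
#' @slot position numeric length-3, um, relative to the cell soma center.
#' @slot view either \code{"granular_layer_sink"} (sums dendrites, soma and
#'   axon hillock, i.e. an electrode within the granule cell cluster) or
#'   \code{"axon_bundle_source"} (sums axonal compartments, i.e. an electrode
#'   within the ascending-axon bundle).
#' @export
setClass("Electrode", representation(position = "numeric", view = "character"))

setValidity("Electrode", function(object) {
  if (length(object@position) != 3 || any(!is.finite(object@position)))
    return("position must be a finite 3-vector (um)")
  if (!object@view %in% c("granular_layer_sink", "axon_bundle_source"))
    return("unknown electrode view")
  TRUE
})

#' Stimulus protocol
#'
#' Mossy-fiber excitation (single pulse or a short high-frequency burst) plus
#' Golgi-like feed-forward inhibition delivered with a fixed delay after the
#' first mossy-fiber spike.
#'
#' @slot mode "single_pulse" or "burst".
#' @slot n_mf number of active mossy fibers (1..4).
#' @slot n_goc number of active inhibitory (Golgi-like) synapses (0..4).
#' @slot rate_hz intra-burst mossy-fiber rate.
#' @slot n_spikes spikes per mossy-fiber burst.
#' @slot onset_ms time of the first mossy-fiber spike within the simulation.
#' @slot goc_delay_ms inhibition onset delay after mossy-fiber onset (ms).
#' @slot goc_pulses IPSPs per inhibitory event.
#' @slot goc_rate_hz intra-burst inhibitory rate.
#' @export
setClass("StimulusProtocol",
         representation(mode = "character", n_mf = "integer", n_goc = "integer",
                        rate_hz = "numeric", n_spikes = "integer",
                        onset_ms = "numeric", goc_delay_ms = "numeric",
                        goc_pulses = "integer", goc_rate_hz = "numeric"))

setValidity("StimulusProtocol", function(object) {
  if (!object@mode %in% c("single_pulse", "burst")) return("unknown mode")
  if (object@n_mf < 1L || object@n_mf > 4L) return("n_mf must be in 1..4")
  if (object@n_goc < 0L || object@n_goc > 4L) return("n_goc must be in 0..4")
  if (object@goc_delay_ms < 0) return("inhibitory delay must be >= 0")
  TRUE
})

#' Plasticity state
#'
#' Expression state of mossy fiber - granule cell long-term plasticity:
#' release probability \code{p} plus a step-wise intrinsic excitability (IE)
#' level realised as scale factors on the closed-state (C_on) and open-state
#' (O_on) Na-inactivation rates: high IE = (0.20, 0.667), low IE =
#' (2.0, 1.333), normal = (1, 1).
#'
#' @slot p release probability in [0, 1].
#' @slot ie_level "low", "normal" or "high".
#' @export
setClass("PlasticityState",
         representation(p = "numeric", ie_level = "character"))

setValidity("PlasticityState", function(object) {
  if (length(object@p) != 1 || is.na(object@p) || object@p < 0 || object@p > 1)
    return("p must be a single value in [0, 1]")
  if (!object@ie_level %in% c("low", "normal", "high"))
    return("ie_level must be one of low/normal/high")
  TRUE
})

#' Compartmental granule-cell model
#'
#' @slot compartments data.frame with one row per compartment: id, group
#'   (dendrite/soma/hillock/axon), parent (0 for root), length and diam (um),
#'   segment end points (x0..z1, um), membrane area (cm^2), synaptic flag.
#' @slot channels list of per-group channel densities (S/cm^2), reversal
#'   potentials and kinetic constants, including the C_on/O_on scales.
#' @slot synparams list of synaptic waveform parameters (nS, ms).
#' @slot protocol StimulusProtocol or NULL until [attachSynapses()] is called.
#' @slot state PlasticityState in force for release sampling.
#' @slot exc_comps,inh_comps compartment ids carrying excitatory / inhibitory
#'   synapses (filled by [attachSynapses()]).
#' @export
setClass("CellModel",
         representation(compartments = "data.frame", channels = "list",
                        synparams = "list", protocol = "ANY", state = "ANY",
                        exc_comps = "integer", inh_comps = "integer"))

setValidity("CellModel", function(object) {
  cp <- object@compartments
  need <- c("id", "group", "parent", "L", "diam", "x0", "y0", "z0",
            "x1", "y1", "z1", "area", "synaptic")
  if (!all(need %in% names(cp))) return("compartment table incomplete")
  if (any(cp$L <= 0) || any(cp$diam <= 0))
    return("compartment length and diameter must be positive")
  if (sum(cp$group == "soma") != 1) return("exactly one soma required")
  if (sum(cp$group == "hillock") < 1) return("hillock missing")
  hk <- cp$parent[cp$group == "hillock"][1]
  if (cp$group[match(hk, cp$id)] != "soma")
    return("hillock must be a child of the soma")
  # structural check: parent must precede child (rooted tree, no cycles)
  if (cp$parent[1] != 0) return("first compartment must be the root")
  if (any(cp$parent[-1] >= cp$id[-1]) || any(cp$parent[-1] < 1))
    return("invalid morphology graph (cycle or orphan)")
  ntip <- sum(cp$synaptic)
  if (ntip != 4) return("each of the 4 dendrites must end in a synaptic tip")
  TRUE
})

#' Per-compartment transmembrane currents from one simulation run
#'
#' @slot im matrix (time step x compartment) of total transmembrane current
#'   (ionic + capacitive + synaptic, outward positive), nA.
#' @slot dt ms. @slot v_soma somatic voltage trace, mV. @slot spikes somatic
#'   spike times (upward 0 mV crossings), ms. @slot injected externally
#'   injected current per step, nA (for the Kirchhoff closure contract).
#' @export
setClass("CompartmentCurrents",
         representation(im = "matrix", dt = "numeric", v_soma = "numeric",
                        spikes = "numeric", injected = "numeric",
                        cell = "ANY"))

#' Single-cell extracellular kernel
#'
#' Extracellular potential (uV) generated by one model granule cell for one
#' mossy-fiber/Golgi input combination, as seen by an electrode view.
#'
#' @slot trace numeric, uV. @slot dt ms. @slot combo integer c(n_mf, n_goc).
#' @slot onset_ms stimulus onset within the trace. @slot electrode Electrode.
#' @export
setClass("Kernel",
         representation(trace = "numeric", dt = "numeric", combo = "integer",
                        onset_ms = "numeric", electrode = "ANY"))

setValidity("Kernel", function(object) {
  if (any(!is.finite(object@trace))) return("kernel trace must be finite")
  TRUE
})

#' Set of kernels over input combinations
#' @slot kernels list of [Kernel-class]. @slot combos integer matrix, one row
#'   per kernel, columns n_mf and n_goc.
#' @export
setClass("KernelSet", representation(kernels = "list", combos = "matrix"))

#' Sampled LFP trace
#'
#' @slot trace numeric, uV. @slot dt ms. @slot onset_ms stimulus onset within
#'   the trace. @slot provenance named list (cluster, jitter, state, seed...).
#' @export
setClass("LfpTrace",
         representation(trace = "numeric", dt = "numeric", onset_ms = "numeric",
                        provenance = "list"))

setValidity("LfpTrace", function(object) {
  if (any(!is.finite(object@trace))) return("trace must be finite")
  if (object@onset_ms < 0 || object@onset_ms > length(object@trace) * object@dt)
    return("onset must fall within the trace")
  TRUE
})

#' Temporal and spatial jitter specification
#'
#' Temporal jitter: normal distribution of granule-cell activation delays
#' (default mean 3 ms, sd 1 ms, the presynaptic neurotransmission delay).
#' Spatial jitter: cell positions uniform in a sphere around the electrode
#' (default radius 15 um, the approximate cluster volume).
#'
#' @slot t_mean,t_sd ms. @slot radius um.
#' @export
setClass("JitterSpec",
         representation(t_mean = "numeric", t_sd = "numeric",
                        radius = "numeric"))

setValidity("JitterSpec", function(object) {
  if (object@t_sd < 0) return("temporal sd must be >= 0")
  if (object@radius <= 0) return("spatial radius must be > 0")
  TRUE
})

#' Granule-cell cluster specification
#'
#' @slot n_cells cells in the cluster (in vivo default 220, in vitro 600).
#' @slot weights fraction of cells receiving 1..4 active mossy fibers
#'   (sums to 1). @slot inhibition logical, Golgi feed-forward inhibition on.
#' @export
setClass("ClusterSpec",
         representation(n_cells = "integer", weights = "numeric",
                        inhibition = "logical"))

setValidity("ClusterSpec", function(object) {
  if (object@n_cells < 1L) return("n_cells must be >= 1")
  if (length(object@weights) != 4) return("weights must have length 4 (n_mf 1..4)")
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (any(object@weights < 0)) return("weights must be non-negative")
  TRUE
})

#' Blind-source-separation result
#'
#' @slot components matrix (4 x time) of recovered source waveforms.
#' @slot mixing matrix (observations x 4). @slot weights recovered w_i per
#'   n_mf (fractions summing to 1). @slot ranges min-max of per-trace
#'   fractions. @slot mse cross-validation waveform MSE, percent.
#' @slot assignment component index assigned to each n_mf 1..4.
#' @slot reliable logical; FALSE when sources look Gaussian (kurtosis check).
#' @export
setClass("BssResult",
         representation(components = "matrix", mixing = "matrix",
                        weights = "numeric", ranges = "matrix",
                        mse = "numeric", per_component_mse = "numeric",
                        assignment = "integer", reliable = "logical",
                        tie = "logical"))

setValidity("BssResult", function(object) {
  if (nrow(object@components) != 4) return("expected 4 components")
  if (abs(sum(object@weights) - 1) > 1e-6) return("weights must sum to 1")
  TRUE
})

#' Band-pass filter specification
#'
#' Zero-phase Butterworth band-pass used for evoked-potential traces
#' (default 100 Hz high-pass, 2 kHz low-pass, order 2 per pass).
#' @export
setClass("FilterSpec",
         representation(highpass = "numeric", lowpass = "numeric",
                        order = "integer", zero_phase = "logical"))

setValidity("FilterSpec", function(object) {
  if (object@highpass < 0 || object@highpass >= object@lowpass)
    return("need 0 <= highpass < lowpass")
  TRUE
})

#' Synthetic evoked-LFP fixture specification
#'
#' Generates in-vivo-like evoked LFP observations by the repetitive-convolution
#' forward model with per-trace connectivity variation and additive Gaussian
#' noise, recording the ground truth for closed-loop tests.
#'
#' @slot n_traces number of observation traces. @slot weights true w_i.
#' @slot noise_sd additive noise sd, uV (post-averaging residual noise).
#' @slot weight_jitter relative sd of per-trace weight variation.
#' @slot tc_delay_ms delay of the C wave (0 = T wave only).
#' @export
setClass("FixtureSpec",
         representation(n_traces = "integer", weights = "numeric",
                        noise_sd = "numeric", weight_jitter = "numeric",
                        tc_delay_ms = "numeric"))

setValidity("FixtureSpec", function(object) {
  if (object@n_traces < 1L) return("n_traces must be >= 1")
  if (abs(sum(object@weights) - 1) > 1e-9) return("weights must sum to 1")
  if (object@noise_sd < 0) return("noise sd must be >= 0")
  TRUE
})

#' Plasticity sweep result
#'
#' Per release-probability grid point and intrinsic-excitability level:
#' T and C wave amplitude change (percent vs control), T-wave lag (ms) and
#' active granule-cell fraction (percent).
#' @slot curve data.frame. @slot control_p numeric.
#' @export
setClass("PlasticityCurve",
         representation(curve = "data.frame", control_p = "numeric"))
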