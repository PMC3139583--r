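#' Default granule-cell morphology
#'
#' Builds the 52-compartment reduced morphology: a spherical soma (modeled as
#' an equivalent cylinder), four dendrites of four compartments each ending in
#' a synaptic tip, an axon hillock below the soma, and an ascending axon of 34
#' compartments. The soma is centered at the origin; dendrites extend upward
#' (+z), the axon downward (-z). Units: um.
#'
#' @param n_dend_seg compartments per dendritic branch (default 4).
#' @param n_axon compartments in the axon (default 34, giving 52 in total).
#' @return data.frame, one row per compartment: id, group, parent, L, diam,
#'   segment end points x0..z1, membrane area (cm^2), synaptic flag.
#' @export
gcMorphology <- function(n_dend_seg = 4L, n_axon = 34L) {
  rows <- list()
  add <- function(group, parent, L, diam, p0, p1, synaptic = FALSE) {
    rows[[length(rows) + 1L]] <<- data.frame(
      id = length(rows) + 1L, group = group, parent = parent, L = L,
      diam = diam, x0 = p0[1], y0 = p0[2], z0 = p0[3],
      x1 = p1[1], y1 = p1[2], z1 = p1[3],
      area = pi * diam * L * 1e-8,  # lateral surface, cm^2
      synaptic = synaptic, stringsAsFactors = FALSE)
    length(rows)
  }
  soma_d <- 5.8
  soma <- add("soma", 0L, soma_d, soma_d,
              c(0, 0, -soma_d / 2), c(0, 0, soma_d / 2))
  # four dendritic branches from the soma apex, 45 degrees elevation
  seg_L <- 15 / n_dend_seg
  for (b in 0:3) {
    az <- b * pi / 2
    dir <- c(cos(az) / sqrt(2), sin(az) / sqrt(2), 1 / sqrt(2))
    parent <- soma
    p0 <- c(0, 0, soma_d / 2)
    for (s in seq_len(n_dend_seg)) {
      p1 <- p0 + dir * seg_L
      parent <- add("dendrite", parent, seg_L, 0.75, p0, p1,
                    synaptic = (s == n_dend_seg))
      p0 <- p1
    }
  }
  hil <- add("hillock", soma, 3, 1.0, c(0, 0, -soma_d / 2),
             c(0, 0, -soma_d / 2 - 3))
  parent <- hil
  z <- -soma_d / 2 - 3
  for (s in seq_len(n_axon)) {
    parent <- add("axon", parent, 3, 0.3, c(0, 0, z), c(0, 0, z - 3))
    z <- z - 3
  }
  do.call(rbind, rows)
}

#' Default channel densities and kinetic constants
#'
#' Per-group maximal conductance densities (S/cm^2) for the reduced channel
#' set: transient Na (m^3 h, with inactivation split into closed-state and
#' open-state pathways carrying the C_on/O_on scale factors), persistent Na,
#' delayed-rectifier K and leak. Na channels are concentrated in the axon
#' hillock (two orders of magnitude above the dendrites), which makes the
#' hillock the spike current sink. Values are calibration choices that realise
#' the behavioral contract of the granule cell (resting near -70 mV, ~1 GOhm
#' input resistance, brief spikes, single spike under feed-forward inhibition
#' and a doublet without it).
#'
#' @return Named list of densities, reversal potentials and kinetics.
#' @export
gcChannels <- function() {
  list(
    density = data.frame(
      group = c("dendrite", "soma", "hillock", "axon"),
      gna   = c(0.004, 0.013, 0.65, 0.02),
      gnap  = c(0, 2.5e-4, 1e-3, 0),
      gkdr  = c(0.004, 0.03, 0.30, 0.04),
      gl    = rep(1 / 3000, 4),
      stringsAsFactors = FALSE),
    ena = 60, ek = -85, el = -70,
    vt = -63,      # activation threshold shift, mV
    q = 2,         # global gating rate scale
    koon = 1,      # weight of the open-state inactivation pathway
    bh_mid = 36,   # Na inactivation-onset midpoint, mV relative to vt
    bh_rate = 1.6, # Na inactivation-onset base rate, 1/ms
    ah_rate = 0.0512, # Na inactivation recovery base rate, 1/ms
    taup = 5,      # persistent-Na activation time constant, ms
    con_scale = 1, oon_scale = 1, ie_level = "normal",
    cm = 1,        # uF/cm^2
    ra = 100       # axial resistivity, Ohm*cm
  )
}

#' Default synaptic waveform and release parameters
#'
#' Double-exponential conductance waveforms for AMPA, NMDA (with sigmoidal
#' voltage-dependent magnesium block) and GABA-A synapses, plus the
#' three-state vesicle-cycle recovery constant. Peak conductances and kinetics
#' are calibration choices (the downstream results depend on the behavioral
#' contract, not on the exact kinetics); the recovery time constant is chosen
#' so that paired-pulse transmission at 300-500 Hz shows mild depression.
#'
#' @return Named list (conductances in nS, times in ms).
#' @export
gcSynapses <- function() {
  list(ampa_g = 0.313, ampa_tr = 0.3, ampa_td = 1.2,
       nmda_g = 0.65, nmda_tr = 6, nmda_td = 18, mg = 1.2,
       gaba_g = 2.5, gaba_tr = 0.5, gaba_td = 12,
       e_exc = 0, e_inh = -75,
       nmda_scale = 1, gaba_scale = 1,
       tau_rec = 20,
       rel_lat_mean = 0.3, rel_lat_sd = 0.2)
}

#' Build a granule-cell model
#'
#' Assembles the reduced multicompartment granule cell: morphology, channel
#' densities and synaptic parameters, each overridable through `config`.
#'
#' @param config optional named list with any of `morphology` (data.frame as
#'   returned by [gcMorphology()]), `channels`, `synapses` (named lists merged
#'   over [gcChannels()] / [gcSynapses()]; `channels$density` rows are matched
#'   by group).
#' @return A [CellModel-class] object without synapses attached.
#' @examples
#' cell <- buildGranuleCell()
#' nrow(cell@compartments)  # 52
#' @export
buildGranuleCell <- function(config = NULL) {
  morph <- gcMorphology()
  chan <- gcChannels()
  syn <- gcSynapses()
  if (!is.null(config)) {
    if (!is.null(config$morphology)) morph <- config$morphology
    if (!is.null(config$channels)) {
      for (nm in names(config$channels)) {
        if (nm == "density") {
          d <- config$channels$density
          for (i in seq_len(nrow(d))) {
            j <- match(d$group[i], chan$density$group)
            if (is.na(j)) stop("unknown compartment group: ", d$group[i])
            for (col in setdiff(names(d), "group"))
              chan$density[j, col] <- d[i, col]
          }
        } else chan[[nm]] <- config$channels[[nm]]
      }
    }
    if (!is.null(config$synapses))
      for (nm in names(config$synapses)) syn[[nm]] <- config$synapses[[nm]]
  }
  cell <- new("CellModel", compartments = morph, channels = chan,
              synparams = syn, protocol = NULL,
              state = plasticityState(1, "normal"),
              exc_comps = integer(0), inh_comps = integer(0))
  validObject(cell)
  cell
}

#' Set the intrinsic excitability level
#'
#' Applies the step-wise intrinsic excitability (IE) change used to model the
#' non-synaptic component of LTP/LTD: the closed-state (C_on) and open-state
#' (O_on) Na-inactivation rates are scaled to (0.20, 0.667) of control for
#' high IE and (2.0, 1.333) for low IE, which shifts the Na steady-state
#' inactivation curve along the voltage axis. All other parameters are
#' untouched.
#'
#' @param cell a [CellModel-class] object.
#' @param level "low", "normal" or "high".
#' @return The modified cell model.
#' @export
setIntrinsicExcitability <- function(cell, level = c("normal", "low", "high")) {
  level <- match.arg(level)
  sc <- ieScales(level)
  cell@channels$con_scale <- unname(sc["con_scale"])
  cell@channels$oon_scale <- unname(sc["oon_scale"])
  cell@channels$ie_level <- level
  if (!is.null(cell@state))
    cell@state <- plasticityState(cell@state@p, level)
  cell
}

#' Attach synapses for a stimulus protocol
#'
#' Places `n_mf` excitatory (AMPA + NMDA) synapses on distinct dendritic tip
#' compartments and `n_goc` inhibitory (GABA-A) synapses on distinct dendritic
#' tips, activated `goc_delay_ms` (default 4 ms) after the mossy fibers. Also
#' fixes the plasticity state used for release sampling and the
#' intrinsic-excitability level of the cell.
#'
#' @param cell a [CellModel-class] object.
#' @param protocol a [StimulusProtocol-class] object.
#' @param state a [PlasticityState-class] object (release probability + IE).
#' @return The cell with synapses attached.
#' @examples
#' cell <- attachSynapses(buildGranuleCell(),
#'                        stimulusProtocol("burst", n_mf = 4, n_goc = 4),
#'                        plasticityState(0.4, "normal"))
#' @export
attachSynapses <- function(cell, protocol, state = plasticityState(0.4, "normal")) {
  stopifnot(is(cell, "CellModel"), is(protocol, "StimulusProtocol"),
            is(state, "PlasticityState"))
  validObject(protocol); validObject(state)
  tips <- cell@compartments$id[cell@compartments$synaptic]
  cell@exc_comps <- tips[seq_len(protocol@n_mf)]
  cell@inh_comps <- if (protocol@n_goc > 0) tips[seq_len(protocol@n_goc)] else integer(0)
  cell@protocol <- protocol
  cell@state <- state
  cell <- setIntrinsicExcitability(cell, state@ie_level)
  cell
}

#' Number of synapse objects attached to a cell
#' @param cell a [CellModel-class] object.
#' @return integer: excitatory + inhibitory synapse count.
#' @export
nSynapses <- function(cell) length(cell@exc_comps) + length(cell@inh_comps)
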