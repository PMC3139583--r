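#' Construct an extracellular medium
#'
#' @param resistivity medium resistivity.
#' @param unit `"Ohm.cm"` (SI-style volume resistivity) or `"MOhm/cm"`, the
#'   convention used in the field-potential literature for granular/pyramidal
#'   layer values (0.1 and 0.26 respectively): the resistance per unit length
#'   of a 1 cm^2 column, numerically 1e6 Ohm.cm per unit.
#' @return A [Medium-class] object.
#' @examples
#' medium(0.1, unit = "MOhm/cm")  # granular-layer default
#' @export
medium <- function(resistivity = 0.1, unit = c("MOhm/cm", "Ohm.cm")) {
  unit <- match.arg(unit)
  rho <- if (unit == "MOhm/cm") resistivity * 1e6 else resistivity
  new("Medium", resistivity = rho)
}

#' Construct a recording electrode
#'
#' Default positions place the granular-layer electrode 10 um lateral to the
#' soma (within the cluster, seeing the spike sink at the axon hillock) and
#' the axon-bundle electrode alongside the ascending axon (seeing the return
#' source). The cell soma is at the origin; the axon runs toward negative z.
#'
#' @param view `"granular_layer_sink"` or `"axon_bundle_source"`.
#' @param position electrode position (um), default per view.
#' @return An [Electrode-class] object.
#' @export
electrode <- function(view = c("granular_layer_sink", "axon_bundle_source"),
                      position = NULL) {
  view <- match.arg(view)
  if (is.null(position))
    position <- if (view == "granular_layer_sink") c(10, 0, 0) else c(6, 0, -60)
  new("Electrode", position = as.numeric(position), view = view)
}

#' Construct a stimulus protocol
#'
#' @param mode `"single_pulse"` (in vitro electrical stimulation) or `"burst"`
#'   (in vivo punctate sensory stimulation).
#' @param n_mf active mossy fibers (1..4).
#' @param n_goc active Golgi-like inhibitory synapses (0..4).
#' @param rate_hz intra-burst mossy fiber rate (burst mode).
#' @param n_spikes spikes per mossy fiber burst (burst mode).
#' @param onset_ms time of the first mossy fiber spike.
#' @param goc_delay_ms feed-forward inhibition delay after mossy fiber onset.
#' @param goc_pulses IPSPs per inhibitory event (in vivo: short burst of 3).
#' @param goc_rate_hz intra-burst inhibitory rate.
#' @return A [StimulusProtocol-class] object.
#' @examples
#' stimulusProtocol("burst", n_mf = 4, n_goc = 4)        # in vivo-like
#' stimulusProtocol("single_pulse", n_mf = 2, n_goc = 3) # in vitro-like
#' @export
stimulusProtocol <- function(mode = c("burst", "single_pulse"),
                             n_mf = 4L, n_goc = 4L,
                             rate_hz = 500, n_spikes = 5L, onset_ms = 10,
                             goc_delay_ms = 4, goc_pulses = NULL,
                             goc_rate_hz = 100) {
  mode <- match.arg(mode)
  if (is.null(goc_pulses)) goc_pulses <- if (mode == "burst") 3L else 1L
  if (mode == "single_pulse") n_spikes <- 1L
  new("StimulusProtocol", mode = mode, n_mf = as.integer(n_mf),
      n_goc = as.integer(n_goc), rate_hz = rate_hz,
      n_spikes = as.integer(n_spikes), onset_ms = onset_ms,
      goc_delay_ms = goc_delay_ms, goc_pulses = as.integer(goc_pulses),
      goc_rate_hz = goc_rate_hz)
}

#' Construct a plasticity state
#'
#' @param p mossy fiber release probability (control 0.4 in vivo, 0.42 as
#'   measured in vitro; raised by LTP, lowered by LTD).
#' @param ie_level intrinsic excitability level: `"normal"`, `"high"` (C_on
#'   scaled to 0.20, O_on to 0.667) or `"low"` (2.0 and 1.333).
#' @return A [PlasticityState-class] object.
#' @examples
#' plasticityState(0.4, "normal")       # naive state
#' plasticityState(0.6, "high")         # LTP expression state
#' plasticityState(0.2, "low")          # LTD expression state
#' @export
plasticityState <- function(p = 0.4, ie_level = c("normal", "low", "high")) {
  ie_level <- match.arg(ie_level)
  new("PlasticityState", p = p, ie_level = ie_level)
}

#' C_on/O_on scale factors for an intrinsic excitability level
#'
#' Maps the step-wise IE level onto scale factors applied to the closed-state
#' (C_on) and open-state (O_on) Na-inactivation rates; scaling these rates
#' shifts the steady-state inactivation curve along the voltage axis.
#'
#' @param ie_level "low", "normal" or "high".
#' @return Named numeric: `con_scale`, `oon_scale`.
#' @export
ieScales <- function(ie_level) {
  switch(ie_level,
         high   = c(con_scale = 0.20, oon_scale = 0.667),
         normal = c(con_scale = 1.0,  oon_scale = 1.0),
         low    = c(con_scale = 2.0,  oon_scale = 1.333),
         stop("unknown intrinsic excitability level: ", ie_level))
}

#' Construct a jitter specification
#'
#' @param t_mean,t_sd temporal jitter of granule-cell activation (ms); default
#'   normal with mean 3 ms and sd 1 ms (presynaptic neurotransmission delay).
#' @param radius radius of the spherical cluster region (um), default 15.
#' @return A [JitterSpec-class] object.
#' @export
jitterSpec <- function(t_mean = 3, t_sd = 1, radius = 15) {
  new("JitterSpec", t_mean = t_mean, t_sd = t_sd, radius = radius)
}

#' Construct a cluster specification
#'
#' @param n_cells granule cells in the cluster; ~220 for the in vivo LFP,
#'   ~600 for the in vitro LFP.
#' @param weights fractions of cells receiving 1..4 active mossy fibers;
#'   defaults to the in vivo connectivity (15/35/35/15 percent).
#' @param inhibition logical, Golgi feed-forward inhibition active.
#' @return A [ClusterSpec-class] object.
#' @export
clusterSpec <- function(n_cells = 220L,
                        weights = c(0.15, 0.35, 0.35, 0.15),
                        inhibition = TRUE) {
  new("ClusterSpec", n_cells = as.integer(n_cells),
      weights = as.numeric(weights), inhibition = inhibition)
}

#' In vivo / in vitro connectivity weights
#'
#' Fractions of granule cells receiving 1..4 active mossy fibers, as estimated
#' by blind source separation from evoked LFPs: 15/35/35/15 percent in vivo,
#' 5/45/35/15 percent in vitro.
#' @param context "invivo" or "invitro".
#' @return Numeric length-4 vector summing to 1.
#' @export
connectivityWeights <- function(context = c("invivo", "invitro")) {
  context <- match.arg(context)
  if (context == "invivo") c(0.15, 0.35, 0.35, 0.15)
  else c(0.05, 0.45, 0.35, 0.15)
}

#' Construct a filter specification
#' @param highpass,lowpass corner frequencies, Hz.
#' @param order Butterworth order per pass.
#' @param zero_phase forward-backward filtering (no peak latency shift).
#' @return A [FilterSpec-class] object.
#' @export
filterSpec <- function(highpass = 100, lowpass = 2000, order = 2L,
                       zero_phase = TRUE) {
  new("FilterSpec", highpass = highpass, lowpass = lowpass,
      order = as.integer(order), zero_phase = zero_phase)
}

#' Construct a fixture specification
#' @param n_traces observation traces to generate (default 14, matching the
#'   size of an in vivo evoked-LFP data set).
#' @param weights true connectivity fractions.
#' @param noise_sd additive Gaussian noise sd (uV) on each averaged trace.
#' @param weight_jitter relative sd of per-trace weight variation (recording
#'   sites sample slightly different clusters).
#' @param tc_delay_ms C-wave delay; 0 generates T-only traces.
#' @return A [FixtureSpec-class] object.
#' @export
fixtureSpec <- function(n_traces = 14L, weights = connectivityWeights("invivo"),
                        noise_sd = 0.5, weight_jitter = 0.1,
                        tc_delay_ms = 0) {
  new("FixtureSpec", n_traces = as.integer(n_traces),
      weights = as.numeric(weights), noise_sd = noise_sd,
      weight_jitter = weight_jitter, tc_delay_ms = tc_delay_ms)
}

#' Construct an LFP trace object
#' @param trace numeric vector, uV.
#' @param dt sampling step, ms.
#' @param onset_ms stimulus onset within the trace, ms.
#' @param provenance named list of generation metadata.
#' @return An [LfpTrace-class] object.
#' @export
lfpTrace <- function(trace, dt, onset_ms = 0, provenance = list()) {
  new("LfpTrace", trace = as.numeric(trace), dt = dt, onset_ms = onset_ms,
      provenance = provenance)
}
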