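# Low-level marshalling between the S4 cell model and the C++ integrator.

.cellArrays <- function(cell) {
  cp <- cell@compartments
  ch <- cell@channels
  dens <- ch$density[match(cp$group, ch$density$group), ]
  area <- cp$area                            # cm^2
  # axial conductance to parent: two half-cylinder resistances in series
  rhalf <- function(i) {
    L <- cp$L[i] * 1e-4 / 2                  # cm
    r <- cp$diam[i] * 1e-4 / 2
    ch$ra * L / (pi * r^2)                   # Ohm
  }
  gax <- numeric(nrow(cp))
  for (i in seq_len(nrow(cp))[-1])
    gax[i] <- 1e6 / (rhalf(i) + rhalf(cp$parent[i]))  # uS
  list(
    morph = list(parent = as.integer(cp$parent - 1L), gax = gax,
                 cap = ch$cm * area * 1e3),  # nF
    chan = list(gna = dens$gna * area * 1e6, gnap = dens$gnap * area * 1e6,
                gkdr = dens$gkdr * area * 1e6, gl = dens$gl * area * 1e6,
                ena = ch$ena, ek = ch$ek, el = ch$el, vt = ch$vt, q = ch$q,
                con_scale = ch$con_scale, oon_scale = ch$oon_scale,
                koon = ch$koon, bh_mid = ch$bh_mid, bh_rate = ch$bh_rate,
                ah_rate = ch$ah_rate,
                taup = ch$taup),
    syn = {
      sp <- cell@synparams
      list(ampa_g = sp$ampa_g * 1e-3, ampa_tr = sp$ampa_tr, ampa_td = sp$ampa_td,
           nmda_g = sp$nmda_g * sp$nmda_scale * 1e-3,
           nmda_tr = sp$nmda_tr, nmda_td = sp$nmda_td, mg = sp$mg,
           gaba_g = sp$gaba_g * sp$gaba_scale * 1e-3,
           gaba_tr = sp$gaba_tr, gaba_td = sp$gaba_td,
           e_exc = sp$e_exc, e_inh = sp$e_inh)
    })
}

#' Sample mossy-fiber release events
#'
#' Draws release events for every attached excitatory synapse under the
#' three-state vesicle cycle: a releasable vesicle is released on a
#' presynaptic spike with probability `p`; after release the site is empty and
#' refills after an exponentially distributed recovery time (mean
#' `tau_rec` ms), which produces mild paired-pulse depression at 300-500 Hz.
#' Each released quantum carries a small synaptic latency (normal, default
#' mean 0.3 ms, sd 0.2 ms, floored at 0.05 ms), the quantal latency
#' variability of the release machinery. Uses the R random number generator:
#' set the seed for reproducibility.
#'
#' @param cell a [CellModel-class] with synapses attached.
#' @return data.frame with columns `comp` (compartment id) and `t` (ms); zero
#'   rows when nothing is released (e.g. p = 0).
#' @export
sampleReleaseEvents <- function(cell) {
  pr <- cell@protocol
  if (is.null(pr)) stop("no synapses attached")
  p <- cell@state@p
  isi <- if (pr@mode == "burst") 1000 / pr@rate_hz else 0
  spk <- pr@onset_ms + (seq_len(pr@n_spikes) - 1) * isi
  tau <- cell@synparams$tau_rec
  lat_m <- cell@synparams$rel_lat_mean
  lat_s <- cell@synparams$rel_lat_sd
  comp <- numeric(0); tt <- numeric(0)
  for (cmp in cell@exc_comps) {
    avail <- -Inf
    for (ts in spk) {
      if (ts >= avail && stats::runif(1) < p) {
        lat <- max(0.05, stats::rnorm(1, lat_m, lat_s))
        comp <- c(comp, cmp); tt <- c(tt, ts + lat)
        avail <- ts + stats::rexp(1, rate = 1 / tau)
      }
    }
  }
  data.frame(comp = as.integer(comp), t = tt)
}

.inhEvents <- function(cell) {
  pr <- cell@protocol
  if (is.null(pr) || length(cell@inh_comps) == 0)
    return(data.frame(comp = integer(0), t = numeric(0)))
  t0 <- pr@onset_ms + pr@goc_delay_ms
  tt <- t0 + (seq_len(pr@goc_pulses) - 1) * 1000 / pr@goc_rate_hz
  data.frame(comp = rep(cell@inh_comps, each = length(tt)),
             t = rep(tt, times = length(cell@inh_comps)))
}

.runIntegrator <- function(cell, duration, dt, exc, inh,
                           stim = NULL, lsa_coef = NULL,
                           return_currents = TRUE, return_voltages = FALSE,
                           v_init = -70, settle_ms = 150) {
  arr <- .cellArrays(cell)
  nsteps <- as.integer(round(duration / dt))
  if (is.null(stim)) stim <- list(amp = 0, t0 = 0, t1 = 0, comp = 1L)
  if (is.null(lsa_coef))
    lsa_coef <- matrix(0, nrow(cell@compartments), 0)
  oe <- order(exc$t); oi <- order(inh$t)
  gc_integrate_cpp(arr$morph, arr$chan, arr$syn,
                   list(exc_comp = as.integer(exc$comp[oe] - 1L),
                        exc_t = exc$t[oe],
                        exc_w = rep(1, length(oe)),
                        inh_comp = as.integer(inh$comp[oi] - 1L),
                        inh_t = inh$t[oi],
                        inh_w = rep(1, length(oi))),
                   dt, nsteps, v_init,
                   stim$amp, stim$t0, stim$t1, as.integer(stim$comp - 1L),
                   lsa_coef, return_currents, return_voltages,
                   settle_ms, 0.5)
}

#' Simulate a granule cell
#'
#' Integrates the compartmental cable model with backward Euler
#' (unconditionally stable; dt must be at most 0.025 ms) and returns the
#' per-compartment total transmembrane current (ionic + capacitive +
#' synaptic) at every step together with the somatic voltage. The currents
#' satisfy the Kirchhoff closure: their sum over compartments equals the
#' externally injected current at every step to machine precision.
#'
#' @param cell a [CellModel-class]; synapses optional (a cell without
#'   synapses is simulated at rest or under `stim`).
#' @param duration_ms total simulated time.
#' @param dt_ms time step, <= 0.025 ms.
#' @param seed optional integer seed for release sampling.
#' @param stim optional somatic current step: list(amp (nA), t0, t1 (ms)).
#' @param v_init initial membrane potential (mV); gating variables start at
#'   their steady state for `v_init`, and the cell is then relaxed for
#'   `settle_ms` at a coarse step before recording, so traces begin at the
#'   true resting state.
#' @param settle_ms pre-stimulus relaxation time (not recorded).
#' @return A [CompartmentCurrents-class] object.
#' @examples
#' cell <- attachSynapses(buildGranuleCell(),
#'                        stimulusProtocol("single_pulse", 4, 4),
#'                        plasticityState(1, "normal"))
#' cc <- simulateCell(cell, duration_ms = 60, seed = 1)
#' length(spikeTimes(cc))
#' @export
simulateCell <- function(cell, duration_ms, dt_ms = 0.025, seed = NULL,
                         stim = NULL, v_init = -70, settle_ms = 150) {
  stopifnot(is(cell, "CellModel"))
  if (dt_ms > 0.025) stop("dt must be <= 0.025 ms")
  if (!is.null(pr <- cell@protocol)) {
    need <- pr@onset_ms + 50
    if (duration_ms < need)
      stop("duration must cover the stimulus plus 50 ms (need >= ",
           need, " ms)")
  }
  if (!is.null(seed)) set.seed(seed)
  exc <- if (is.null(cell@protocol)) data.frame(comp = integer(0), t = numeric(0))
         else sampleReleaseEvents(cell)
  inh <- .inhEvents(cell)
  if (!is.null(stim)) stim$comp <- 1L
  res <- .runIntegrator(cell, duration_ms, dt_ms, exc, inh, stim = stim,
                        return_currents = TRUE, v_init = v_init,
                        settle_ms = settle_ms)
  nsteps <- length(res$v_soma)
  tvec <- (seq_len(nsteps) - 1) * dt_ms
  inj <- numeric(nsteps)
  if (!is.null(stim) && stim$amp != 0)
    inj[tvec >= stim$t0 & tvec < stim$t1] <- stim$amp
  new("CompartmentCurrents", im = res$im, dt = dt_ms, v_soma = res$v_soma,
      spikes = res$spikes, injected = inj, cell = cell)
}

#' Rheobase by bisection
#'
#' Finds the minimal somatic step-current amplitude that elicits a spike
#' (upward 0 mV crossing), by bisection to within `tol_nA`.
#'
#' @param cell a [CellModel-class] (synapse-free copy is used).
#' @param step_ms duration of the current step.
#' @param upper_nA initial upper bracket, nA.
#' @param tol_nA bisection tolerance (default 0.001 nA = 1 pA).
#' @return Rheobase current in nA.
#' @export
rheobase <- function(cell, step_ms = 100, upper_nA = 0.08, tol_nA = 1e-3) {
  cell@protocol <- NULL
  cell@exc_comps <- integer(0); cell@inh_comps <- integer(0)
  spikes_at <- function(amp) {
    cc <- simulateCell(cell, duration_ms = step_ms + 20,
                       stim = list(amp = amp, t0 = 10, t1 = 10 + step_ms))
    length(cc@spikes) > 0
  }
  lo <- 0; hi <- upper_nA
  if (!spikes_at(hi)) stop("no spike at the upper bracket; raise upper_nA")
  while (hi - lo > tol_nA) {
    mid <- (lo + hi) / 2
    if (spikes_at(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Total synaptic charge of a simulation
#'
#' Integral over time of the summed transmembrane current of the synaptic tip
#' compartments relative to an event-free run; used to verify that p = 0
#' transmits nothing.
#'
#' @param cell a [CellModel-class] with synapses attached.
#' @param duration_ms,dt_ms,seed as in [simulateCell()].
#' @return charge in nA*ms.
#' @export
synapticCharge <- function(cell, duration_ms = 80, dt_ms = 0.025, seed = 1) {
  cc <- simulateCell(cell, duration_ms, dt_ms, seed = seed)
  ref <- cell; ref@protocol <- NULL
  ref@exc_comps <- integer(0); ref@inh_comps <- integer(0)
  cc0 <- simulateCell(ref, duration_ms, dt_ms)
  tips <- cell@compartments$id[cell@compartments$synaptic]
  sum(cc@im[, tips] - cc0@im[, tips]) * dt_ms
}
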