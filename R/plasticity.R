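# Plasticity scenarios: per-cell stochastic cluster simulations, LFP
# amplitude/lag measures and release-probability sweeps.

.scenarioDefaults <- function(scenario) {
  switch(scenario,
    invivo_T = list(n_clusters = 1L, cluster = clusterSpec(220L),
                    protocol = stimulusProtocol("burst", rate_hz = 500,
                                                n_spikes = 5L, onset_ms = 10)),
    invivo_TC = list(n_clusters = 2L, cluster = clusterSpec(220L),
                     protocol = stimulusProtocol("burst", rate_hz = 500,
                                                 n_spikes = 5L, onset_ms = 10)),
    invitro = list(n_clusters = 1L,
                   cluster = clusterSpec(600L, connectivityWeights("invitro")),
                   protocol = stimulusProtocol("single_pulse", onset_ms = 10)),
    stop("unknown scenario: ", scenario))
}

# Simulate one cluster realization: every granule cell is an independent
# stochastic draw (mossy-fiber count, release sampling, activation delay,
# position), not a scaled copy.  Returns the summed sink-view LFP and the
# per-cell spike counts.
.simulateCluster <- function(cells, coef, cluster, jitter, duration, dt) {
  n <- cluster@n_cells
  combo_of <- sample.int(4L, n, replace = TRUE, prob = cluster@weights)
  delays <- stats::rnorm(n, jitter@t_mean, jitter@t_sd)
  pos <- .sampleSphere(n, jitter@radius)
  r0 <- sqrt(sum(cells$electrode@position^2))
  att <- .attenuation(sqrt(rowSums(pos^2)), r0)
  nsteps <- as.integer(round(duration / dt))
  acc <- numeric(nsteps)
  nspk <- integer(n)
  t_first <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    cell <- cells$by_nmf[[combo_of[j]]]
    exc <- sampleReleaseEvents(cell)
    inh <- .inhEvents(cell)
    r <- .runIntegrator(cell, duration, dt, exc, inh, lsa_coef = coef,
                        return_currents = FALSE)
    k <- round(delays[j] / dt)
    tr <- r$phi[, 1]
    shifted <- if (k >= 0) c(numeric(k), tr)[seq_len(nsteps)]
               else c(tr[-seq_len(-k)], numeric(-k))
    acc <- acc + att[j] * shifted
    nspk[j] <- length(r$spikes)
    if (nspk[j] > 0) t_first[j] <- r$spikes[1] + delays[j]
  }
  list(lfp = acc, nspk = nspk, combo = combo_of, t_first = t_first)
}

#' Run a plasticity scenario
#'
#' Simulates the evoked LFP of one (or two, for the T+C case) granule-cell
#' cluster under a plasticity state. Every cluster cell is an independent
#' stochastic realization of the model (mossy-fiber count drawn from the
#' connectivity weights with the complementary 5 - n_mf inhibitory count,
#' release sampled at the state's p, activation delay and position jittered).
#' The trace is averaged over `n_reps` repetitions and a 100 ms silent
#' baseline precedes the stimulus so that amplitudes can be measured against
#' the pre-stimulus mean. For the T+C scenario the C cluster is simulated
#' independently (independent inhibition) and summed with a 10 ms delay.
#'
#' @param state a [PlasticityState-class].
#' @param scenario `"invivo_T"` (single cluster, 500 Hz burst),
#'   `"invivo_TC"` (two clusters, C delayed 10 ms) or `"invitro"`
#'   (600 cells, single pulse).
#' @param n_reps repetitions averaged (default 15).
#' @param seed integer seed (all randomness derives from it).
#' @param cluster optional [ClusterSpec-class] override.
#' @param jitter a [JitterSpec-class].
#' @param electrode,medium forward-model geometry.
#' @param tc_delay_ms C-wave delay for `invivo_TC`.
#' @param cell_config optional config list for [buildGranuleCell()].
#' @return list: `lfp` (averaged [LfpTrace-class]), `spike_log` (data.frame
#'   rep/cluster/cell/n_mf/n_spikes/t_first_ms, first-spike time in the
#'   cluster time base), `reps` (matrix of per-rep traces).
#' @export
runState <- function(state, scenario = c("invivo_T", "invivo_TC", "invitro"),
                     n_reps = 15, seed = 1, cluster = NULL,
                     jitter = jitterSpec(), electrode = grclfp::electrode(),
                     medium = grclfp::medium(), tc_delay_ms = 10,
                     cell_config = NULL) {
  scenario <- match.arg(scenario)
  def <- .scenarioDefaults(scenario)
  if (is.null(cluster)) cluster <- def$cluster
  protocol <- def$protocol
  set.seed(seed)
  dt <- 0.025
  duration <- protocol@onset_ms + 45
  baseline_ms <- 100
  cell0 <- buildGranuleCell(cell_config)
  coef <- matrix(viewCoefficients(cell0, electrode, medium), ncol = 1)
  by_nmf <- lapply(1:4, function(nmf) {
    pr <- protocol
    pr@n_mf <- as.integer(nmf)
    pr@n_goc <- if (cluster@inhibition) 5L - as.integer(nmf) else 0L
    attachSynapses(cell0, pr, state)
  })
  cells <- list(by_nmf = by_nmf, electrode = electrode)
  pad <- as.integer(round((baseline_ms - protocol@onset_ms) / dt))
  ntot <- as.integer(round(duration / dt)) + pad +
          if (scenario == "invivo_TC") round(tc_delay_ms / dt) else 0L
  reps <- matrix(0, ntot, n_reps)
  logs <- list()
  for (r in seq_len(n_reps)) {
    clT <- .simulateCluster(cells, coef, cluster, jitter, duration, dt)
    tr <- c(numeric(pad), clT$lfp)
    logs[[length(logs) + 1L]] <-
      data.frame(rep = r, cluster = "T", cell = seq_along(clT$nspk),
                 n_mf = clT$combo, n_spikes = clT$nspk,
                 t_first_ms = clT$t_first)
    if (scenario == "invivo_TC") {
      clC <- .simulateCluster(cells, coef, cluster, jitter, duration, dt)
      kC <- round(tc_delay_ms / dt)
      trC <- c(numeric(pad + kC), clC$lfp)
      tr <- c(tr, numeric(ntot - length(tr)))
      tr[seq_along(trC)] <- tr[seq_along(trC)] + trC
      logs[[length(logs) + 1L]] <-
        data.frame(rep = r, cluster = "C", cell = seq_along(clC$nspk),
                   n_mf = clC$combo, n_spikes = clC$nspk,
                   t_first_ms = clC$t_first)
    }
    reps[seq_along(tr), r] <- tr
  }
  avg <- rowMeans(reps)
  lfp <- new("LfpTrace", trace = avg, dt = dt, onset_ms = baseline_ms,
             provenance = list(scenario = scenario, p = state@p,
                               ie = state@ie_level, n_reps = n_reps,
                               seed = seed, n_cells = cluster@n_cells,
                               inhibition = cluster@inhibition))
  list(lfp = lfp, spike_log = do.call(rbind, logs), reps = reps)
}

#' Fraction of discharging granule cells
#'
#' 100 x (cells with at least one spike) / (cells simulated), evaluated on a
#' spike log from [runState()]. By default only the T cluster enters the
#' count (the percentage is defined per cluster).
#'
#' @param spike_log data.frame from [runState()].
#' @param cluster_id cluster label to evaluate (`"T"` by default; `NULL`
#'   pools all clusters).
#' @return percentage, 0..100.
#' @export
activeFraction <- function(spike_log, cluster_id = "T") {
  if (nrow(spike_log) == 0) stop("empty spike log")
  if (!is.null(cluster_id))
    spike_log <- spike_log[spike_log$cluster %in% cluster_id, ]
  100 * mean(spike_log$n_spikes > 0)
}

#' Peak amplitudes and lag of the T and C waves
#'
#' Measures the T (and optionally C) wave of an evoked LFP relative to the
#' mean of the `baseline_ms` window preceding stimulus onset, as magnitudes
#' of the largest baseline-subtracted deflection in each search window.
#' The T lag is the time from stimulus onset to the T peak.
#'
#' @param trace an [LfpTrace-class].
#' @param baseline_ms baseline window length before onset (default 100).
#' @param t_window_ms search window for the T peak after onset.
#' @param c_window_ms search window (after onset) for the C peak; NULL skips
#'   the C measurement (single-wave traces).
#' @param tc_delay_ms start of the C window after onset.
#' @return list: `t_amp`, `c_amp` (uV, baseline-subtracted magnitudes;
#'   0 for flat traces), `t_lag_ms` (NA-flagged when undefined), `t_sign`.
#' @export
amplitudeAndLag <- function(trace, baseline_ms = 100, t_window_ms = 10,
                            c_window_ms = 25, tc_delay_ms = 10) {
  dt <- trace@dt
  on <- trace@onset_ms
  if (on < baseline_ms) stop("baseline window precedes the trace start")
  i_on <- round(on / dt) + 1L
  ib <- seq(i_on - round(baseline_ms / dt), i_on - 1L)
  base <- mean(trace@trace[ib])
  win <- function(from, to) {
    idx <- seq(i_on + round(from / dt),
               min(i_on + round(to / dt), length(trace@trace)))
    d <- trace@trace[idx] - base
    j <- which.max(abs(d))
    list(amp = abs(d[j]), sign = sign(d[j]),
         lag = (idx[j] - i_on) * dt, flat = max(abs(d)) < 1e-12)
  }
  tw <- win(0, t_window_ms)
  out <- list(t_amp = if (tw$flat) 0 else tw$amp,
              t_lag_ms = if (tw$flat) NA_real_ else tw$lag,
              t_sign = tw$sign)
  if (!is.null(c_window_ms)) {
    cw <- win(tc_delay_ms, tc_delay_ms + c_window_ms)
    out$c_amp <- if (cw$flat) 0 else cw$amp
    out$c_sign <- cw$sign
  }
  out
}

#' Sweep release probability and intrinsic excitability
#'
#' Regenerates the scenario LFP over a grid of release probabilities and IE
#' levels and measures T/C amplitude change versus the control point, T lag
#' and active fraction.
#'
#' @param p_grid release probabilities (must cover `control_p`).
#' @param ie_levels subset of c("low", "normal", "high").
#' @param scenario as in [runState()].
#' @param control_p control release probability (amplitude changes are
#'   relative to (control_p, "normal")).
#' @param n_reps repetitions per grid point.
#' @param seed base seed; each grid point derives its own.
#' @param ... passed to [runState()].
#' @return A [PlasticityCurve-class].
#' @export
sweepPlasticity <- function(p_grid = seq(0, 1, 0.1),
                            ie_levels = c("low", "normal", "high"),
                            scenario = "invivo_T", control_p = 0.4,
                            n_reps = 15, seed = 1, ...) {
  if (!any(abs(p_grid - control_p) < 1e-9))
    p_grid <- sort(c(p_grid, control_p))
  grid <- expand.grid(p = p_grid, ie = ie_levels,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    st <- plasticityState(grid$p[i], grid$ie[i])
    rs <- runState(st, scenario, n_reps = n_reps,
                   seed = seed + 1000L * i, ...)
    m <- amplitudeAndLag(lowpassAverage(rs$lfp),
                         c_window_ms = if (scenario == "invivo_TC") 25 else NULL)
    data.frame(p = grid$p[i], ie = grid$ie[i], t_amp = m$t_amp,
               c_amp = if (is.null(m$c_amp)) NA_real_ else m$c_amp,
               t_lag_ms = m$t_lag_ms,
               active_pct = activeFraction(rs$spike_log))
  })
  curve <- do.call(rbind, rows)
  ctrl <- curve[abs(curve$p - control_p) < 1e-9 & curve$ie == "normal", ]
  curve$t_amp_change_pct <- 100 * (curve$t_amp / ctrl$t_amp[1] - 1)
  curve$c_amp_change_pct <- 100 * (curve$c_amp / ctrl$c_amp[1] - 1)
  new("PlasticityCurve", curve = curve, control_p = control_p)
}

#' Low-pass filter an averaged LFP for measurement
#'
#' Simulated LFP measurements are taken after averaging and 2 kHz low-pass
#' filtering, mirroring the treatment of experimental traces (the 100 Hz
#' high-pass that stabilises recording baselines is unnecessary for model
#' traces, whose baseline is exactly flat).
#'
#' @param trace an [LfpTrace-class].
#' @param lowpass_hz corner frequency.
#' @return the filtered [LfpTrace-class].
#' @export
lowpassAverage <- function(trace, lowpass_hz = 2000) {
  filterTrace(trace, filterSpec(highpass = 0, lowpass = lowpass_hz))
}
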