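# Population LFP synthesis by repetitive convolution: single-cell kernels ->
# temporal jitter -> connectivity-weighted single-neuron field -> spatial
# jitter over the cluster -> ensemble LFP.

#' Representative and full input-combination sets
#'
#' With 1-4 mossy fibers and 0-4 Golgi-like inhibitory inputs there are 20
#' independent combinations; many responses are redundant, and the four
#' complementary pairings 1/4, 2/3, 3/2, 4/1 are sufficient to reconstruct
#' the inhibited LFP. `representativeCombos(FALSE)` gives their uninhibited
#' counterparts 1/0..4/0.
#'
#' @param inhibited logical; paired inhibition (TRUE) or none (FALSE).
#' @return integer matrix with columns `n_mf`, `n_goc`.
#' @export
representativeCombos <- function(inhibited = TRUE) {
  m <- cbind(n_mf = 1:4, n_goc = if (inhibited) 4:1 else rep(0L, 4))
  storage.mode(m) <- "integer"
  m
}

#' @rdname representativeCombos
#' @export
fullCombos <- function() {
  g <- expand.grid(n_mf = 1:4, n_goc = 0:4)
  m <- cbind(n_mf = g$n_mf, n_goc = g$n_goc)
  storage.mode(m) <- "integer"
  m
}

#' Generate single-cell kernels for a set of input combinations
#'
#' Simulates the granule-cell model once per (n_mf, n_goc) combination under
#' the given plasticity state and composes the extracellular kernel seen by
#' the electrode. Release sampling uses the R random number generator, so a
#' fixed seed gives bit-identical kernels.
#'
#' @param combos integer matrix (columns n_mf, n_goc), default the four
#'   representative inhibited pairings plus their uninhibited counterparts.
#' @param state a [PlasticityState-class].
#' @param protocol a [StimulusProtocol-class] template; its n_mf/n_goc are
#'   overridden per combo.
#' @param electrode an [Electrode-class]. @param medium a [Medium-class].
#' @param duration_ms simulated time (must cover stimulus + 50 ms).
#' @param dt_ms time step. @param seed optional RNG seed.
#' @param cell_config optional config list passed to [buildGranuleCell()].
#' @return A [KernelSet-class].
#' @examples
#' \donttest{
#' ks <- generateKernelSet(representativeCombos(), seed = 1)
#' length(ks@kernels)  # 4
#' }
#' @export
generateKernelSet <- function(combos = rbind(representativeCombos(TRUE),
                                             representativeCombos(FALSE)),
                              state = plasticityState(0.4, "normal"),
                              protocol = stimulusProtocol("burst"),
                              electrode = grclfp::electrode(),
                              medium = grclfp::medium(),
                              duration_ms = NULL, dt_ms = 0.025, seed = NULL,
                              cell_config = NULL) {
  stopifnot(ncol(combos) == 2, all(combos[, 1] %in% 1:4),
            all(combos[, 2] %in% 0:4))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(duration_ms)) duration_ms <- protocol@onset_ms + 55
  cell0 <- buildGranuleCell(cell_config)
  coef <- matrix(viewCoefficients(cell0, electrode, medium), ncol = 1)
  kernels <- lapply(seq_len(nrow(combos)), function(i) {
    pr <- protocol
    pr@n_mf <- combos[i, 1]; pr@n_goc <- combos[i, 2]
    cell <- attachSynapses(cell0, pr, state)
    exc <- sampleReleaseEvents(cell)
    inh <- .inhEvents(cell)
    r <- .runIntegrator(cell, duration_ms, dt_ms, exc, inh, lsa_coef = coef,
                        return_currents = FALSE)
    new("Kernel", trace = as.numeric(r$phi[, 1]), dt = dt_ms,
        combo = as.integer(combos[i, ]), onset_ms = protocol@onset_ms,
        electrode = electrode)
  })
  new("KernelSet", kernels = kernels, combos = combos)
}

#' Convolve a kernel with temporal jitter
#'
#' Discrete convolution of a single-cell kernel with the sampled density of
#' the activation-delay distribution (normal, default mean 3 ms, sd 1 ms).
#' The density is renormalised on the sampling grid so the trace integral is
#' preserved; with sd = 0 this reduces to a pure shift by the mean delay.
#'
#' @param kernel a [Kernel-class] (or numeric trace with `dt` attribute).
#' @param jitter a [JitterSpec-class].
#' @return A [Kernel-class] with the jittered trace (same length; a warning
#'   flags tail truncation when the jitter support exceeds the trace).
#' @export
temporalConvolve <- function(kernel, jitter = jitterSpec()) {
  tr <- kernel@trace
  dt <- kernel@dt
  n <- length(tr)
  if (jitter@t_sd <= 0) {
    k <- round(jitter@t_mean / dt)
    out <- c(numeric(k), tr)[seq_len(n)]
  } else {
    tmax <- jitter@t_mean + 5 * jitter@t_sd
    tk <- seq(0, tmax, by = dt)
    dens <- stats::dnorm(tk, jitter@t_mean, jitter@t_sd)
    dens <- dens / sum(dens)
    nd <- length(tk)
    if (nd > n)
      warning("jitter support exceeds trace length; tail padded/truncated")
    # causal FIR: out[i] = sum_j dens[j] * tr[i - j + 1]
    x <- c(numeric(nd - 1), tr)
    y <- stats::filter(x, dens, method = "convolution", sides = 1)
    out <- as.numeric(y[(nd - 1) + seq_len(n)])
  }
  new("Kernel", trace = out, dt = dt, combo = kernel@combo,
      onset_ms = kernel@onset_ms, electrode = kernel@electrode)
}

#' Weighted single-neuron field
#'
#' Weights and sums jittered kernels with the connectivity fractions w_i
#' (fraction of cells receiving i mossy fibers) to form the prototypical
#' field response of one granule cell in the cluster.
#'
#' @param kernels list of 4 [Kernel-class] objects ordered n_mf = 1..4 (or a
#'   [KernelSet-class] whose combos cover n_mf 1..4 once each).
#' @param w numeric length-4 connectivity fractions, summing to 1.
#' @return A [Kernel-class] holding the weighted field.
#' @export
singleNeuronField <- function(kernels, w) {
  if (is(kernels, "KernelSet")) {
    ord <- order(kernels@combos[, 1])
    stopifnot(all(kernels@combos[ord, 1] == 1:4))
    kernels <- kernels@kernels[ord]
  }
  stopifnot(length(kernels) == 4, abs(sum(w) - 1) < 1e-9)
  tr <- Reduce(`+`, Map(function(k, wi) wi * k@trace, kernels, as.list(w)))
  k1 <- kernels[[1]]
  new("Kernel", trace = tr, dt = k1@dt, combo = c(NA_integer_, NA_integer_),
      onset_ms = k1@onset_ms, electrode = k1@electrode)
}

# distance attenuation relative to the kernel's reference electrode distance:
# point-source 1/(4 pi sigma r) scaling with r floored at rmin
.attenuation <- function(r, r0, rmin = 1) r0 / pmax(r, rmin)

.sampleSphere <- function(n, radius) {
  r <- radius * stats::runif(n)^(1 / 3)
  u <- stats::rnorm(n); v <- stats::rnorm(n); w <- stats::rnorm(n)
  nrm <- sqrt(u^2 + v^2 + w^2)
  cbind(x = r * u / nrm, y = r * v / nrm, z = r * w / nrm)
}

#' Spatial convolution over the granule-cell cluster
#'
#' Draws `n_cells` positions uniformly in the cluster sphere (electrode at
#' the center), scales the single-neuron field by the point-source distance
#' attenuation of each cell (relative to the kernel's reference electrode
#' distance, floored at 1 um) and sums, yielding the ensemble LFP.
#'
#' @param field a [Kernel-class] from [singleNeuronField()].
#' @param cluster a [ClusterSpec-class].
#' @param jitter a [JitterSpec-class] (spatial radius).
#' @param seed optional RNG seed.
#' @return An [LfpTrace-class].
#' @export
spatialConvolve <- function(field, cluster, jitter = jitterSpec(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r0 <- sqrt(sum(field@electrode@position^2))
  pos <- .sampleSphere(cluster@n_cells, jitter@radius)
  att <- .attenuation(sqrt(rowSums(pos^2)), r0)
  new("LfpTrace", trace = field@trace * sum(att), dt = field@dt,
      onset_ms = field@onset_ms,
      provenance = list(n_cells = cluster@n_cells, radius = jitter@radius,
                        seed = seed, scale = sum(att)))
}

#' Assemble the T + C evoked LFP
#'
#' Linear sum of the trigeminal (T) and cortical (C) cluster LFPs with C
#' shifted by the cortico-ponto-cerebellar delay (default 10 ms). Either
#' component may carry sink or source polarity depending on its cluster
#' position relative to the electrode.
#'
#' @param lfp_T,lfp_C [LfpTrace-class] objects with equal dt.
#' @param delay_ms delay of C relative to T.
#' @return An [LfpTrace-class] with the onset of T.
#' @export
assembleTC <- function(lfp_T, lfp_C, delay_ms = 10) {
  if (abs(lfp_T@dt - lfp_C@dt) > 1e-12) stop("mismatched sampling intervals")
  k <- round(delay_ms / lfp_T@dt)
  n <- max(length(lfp_T@trace), length(lfp_C@trace) + k)
  tr <- numeric(n)
  tr[seq_along(lfp_T@trace)] <- lfp_T@trace
  idx <- seq_along(lfp_C@trace) + k
  tr[idx] <- tr[idx] + lfp_C@trace
  new("LfpTrace", trace = tr, dt = lfp_T@dt, onset_ms = lfp_T@onset_ms,
      provenance = c(lfp_T@provenance, list(tc_delay_ms = delay_ms)))
}

#' Full repetitive-convolution LFP
#'
#' Convenience chain over the five synthesis steps: kernels for n_mf 1..4 at
#' the cluster's inhibition setting, temporal jitter, connectivity weighting,
#' spatial jitter, ensemble sum.
#'
#' @param cluster a [ClusterSpec-class]. @param state [PlasticityState-class].
#' @param protocol a [StimulusProtocol-class] template.
#' @param jitter a [JitterSpec-class]. @param electrode an [Electrode-class].
#' @param medium a [Medium-class]. @param seed RNG seed.
#' @param kernels optional precomputed [KernelSet-class] (n_mf 1..4).
#' @return An [LfpTrace-class].
#' @export
reconvLfp <- function(cluster = clusterSpec(),
                      state = plasticityState(0.4, "normal"),
                      protocol = stimulusProtocol("burst"),
                      jitter = jitterSpec(),
                      electrode = grclfp::electrode(),
                      medium = grclfp::medium(), seed = NULL,
                      kernels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(kernels))
    kernels <- generateKernelSet(representativeCombos(cluster@inhibition),
                                 state = state, protocol = protocol,
                                 electrode = electrode, medium = medium)
  jit <- lapply(kernels@kernels[order(kernels@combos[, 1])],
                temporalConvolve, jitter = jitter)
  field <- singleNeuronField(jit, cluster@weights)
  spatialConvolve(field, cluster, jitter)
}
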