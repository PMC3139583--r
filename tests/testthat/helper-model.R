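# Shared fixtures: built once per test run.  Short protocols keep single
# simulations in the tens of milliseconds.

.cache <- new.env(parent = emptyenv())

cachedCell <- function() {
  if (is.null(.cache$cell)) .cache$cell <- buildGranuleCell()
  .cache$cell
}

# in vitro-style single pulse, deterministic release (p = 1)
pulseCell <- function(n_mf = 4, n_goc = 4, p = 1, ie = "normal",
                      onset = 15) {
  attachSynapses(cachedCell(),
                 stimulusProtocol("single_pulse", n_mf, n_goc,
                                  onset_ms = onset),
                 plasticityState(p, ie))
}

# in vivo-style 500 Hz burst
burstCell <- function(n_mf = 4, n_goc = 4, p = 0.4, ie = "normal",
                      onset = 10) {
  attachSynapses(cachedCell(),
                 stimulusProtocol("burst", n_mf, n_goc, rate_hz = 500,
                                  n_spikes = 3L, onset_ms = onset),
                 plasticityState(p, ie))
}

cachedPulseRun <- function() {
  if (is.null(.cache$pulse_run))
    .cache$pulse_run <- simulateCell(pulseCell(), 70, seed = 1)
  .cache$pulse_run
}

# small kernel set shared across reconv/bss tests
cachedKernels <- function() {
  if (is.null(.cache$kernels))
    .cache$kernels <- generateKernelSet(
      representativeCombos(TRUE), seed = 11,
      protocol = stimulusProtocol("burst", rate_hz = 500, n_spikes = 3L,
                                  onset_ms = 10),
      state = plasticityState(0.42, "normal"))
  .cache$kernels
}

amariIndex <- function(P) {
  # Amari performance index of P = W_est %*% A_true; 0 iff P is a scaled
  # permutation
  P <- abs(P)
  n <- nrow(P)
  rowterm <- sum(rowSums(P / apply(P, 1, max)) - 1)
  colterm <- sum(colSums(t(t(P) / apply(P, 2, max))) - 1)
  (rowterm + colterm) / (2 * n * (n - 1))
}
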