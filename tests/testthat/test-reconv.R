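test_that("kernel sets cover the requested combinations", {
  ks <- cachedKernels()
  expect_equal(length(ks@kernels), 4)
  expect_equal(ks@combos, representativeCombos(TRUE))
  expect_equal(nrow(fullCombos()), 20)
  expect_equal(nrow(unique(fullCombos())), 20)
})

test_that("kernel generation is bit-identical under a fixed seed", {
  pr <- stimulusProtocol("burst", rate_hz = 500, n_spikes = 3L, onset_ms = 10)
  k1 <- generateKernelSet(representativeCombos()[1:2, ], seed = 5,
                          protocol = pr)
  k2 <- generateKernelSet(representativeCombos()[1:2, ], seed = 5,
                          protocol = pr)
  expect_identical(k1@kernels[[1]]@trace, k2@kernels[[1]]@trace)
  expect_identical(k1@kernels[[2]]@trace, k2@kernels[[2]]@trace)
})

test_that("zero-sd temporal jitter is a pure shift by the mean delay", {
  k <- cachedKernels()@kernels[[4]]
  out <- temporalConvolve(k, jitterSpec(t_mean = 3, t_sd = 0))
  shift <- round(3 / k@dt)
  expect_equal(out@trace[(shift + 1):length(out@trace)],
               k@trace[1:(length(k@trace) - shift)])
})

test_that("temporal jitter preserves the integral and adds variance", {
  k <- cachedKernels()@kernels[[4]]
  # zero-pad so the jittered mass stays inside the trace
  kp <- k
  kp@trace <- c(k@trace, numeric(round(15 / k@dt)))
  outp <- temporalConvolve(kp, jitterSpec())
  expect_equal(sum(outp@trace), sum(kp@trace), tolerance = 1e-3)
  out <- temporalConvolve(k, jitterSpec())
  # Gaussian bump of width w -> width^2 grows by the jitter variance (2%)
  dt <- 0.025
  tt <- seq(0, 60, dt)
  w <- 2
  bump <- new("Kernel", trace = dnorm(tt, 20, w), dt = dt,
              combo = c(1L, 0L), onset_ms = 0, electrode = electrode())
  out2 <- temporalConvolve(bump, jitterSpec(t_mean = 3, t_sd = 1))
  m <- sum(tt * out2@trace) / sum(out2@trace)
  v <- sum((tt - m)^2 * out2@trace) / sum(out2@trace)
  expect_equal(v, w^2 + 1^2, tolerance = 0.02)
  # smoothing strictly reduces the peak
  expect_lt(max(abs(out@trace)), max(abs(k@trace)))
})

test_that("one-hot weights return the corresponding jittered kernel", {
  ks <- cachedKernels()
  jit <- lapply(ks@kernels[order(ks@combos[, 1])], temporalConvolve)
  f <- singleNeuronField(jit, c(0, 0, 1, 0))
  expect_equal(f@trace, jit[[3]]@trace)
  # weighting is linear in the weights
  f2 <- singleNeuronField(jit, c(0.25, 0.25, 0.25, 0.25))
  expect_equal(f2@trace,
               0.25 * Reduce(`+`, lapply(jit, function(k) k@trace)))
})

test_that("a single cell at the electrode reproduces the reference scaling", {
  ks <- cachedKernels()
  jit <- lapply(ks@kernels[order(ks@combos[, 1])], temporalConvolve)
  f <- singleNeuronField(jit, connectivityWeights("invivo"))
  # with the position forced to the center, attenuation = r0 / rmin
  set.seed(1)
  lfp <- spatialConvolve(f, clusterSpec(1L), jitterSpec(radius = 1e-9))
  r0 <- sqrt(sum(f@electrode@position^2))
  expect_equal(lfp@trace, f@trace * r0 / 1, tolerance = 1e-6)
})

test_that("expected LFP amplitude grows linearly with cluster size", {
  # Monte-Carlo oracle for E[sum of attenuations]: n * E[r0/max(r, 1)]
  set.seed(42)
  r0 <- 10; R <- 15
  draws <- r0 / pmax(R * runif(1e5)^(1 / 3), 1)
  e_att <- mean(draws)
  ks <- cachedKernels()
  jit <- lapply(ks@kernels[order(ks@combos[, 1])], temporalConvolve)
  f <- singleNeuronField(jit, connectivityWeights("invivo"))
  for (n in c(50, 200)) {
    set.seed(7)
    peaks <- replicate(40, {
      lfp <- spatialConvolve(f, clusterSpec(n))
      max(abs(lfp@trace))
    })
    expect_equal(mean(peaks), n * e_att * max(abs(f@trace)),
                 tolerance = 0.05)
  }
})

test_that("the ensemble LFP is linear in the kernels and reproducible", {
  ks <- cachedKernels()
  lfp1 <- reconvLfp(kernels = ks, seed = 3)
  lfp1b <- reconvLfp(kernels = ks, seed = 3)
  expect_identical(lfp1@trace, lfp1b@trace)
  ks2 <- ks
  ks2@kernels <- lapply(ks@kernels, function(k) { k@trace <- 2 * k@trace; k })
  lfp2 <- reconvLfp(kernels = ks2, seed = 3)
  expect_equal(lfp2@trace, 2 * lfp1@trace, tolerance = 1e-12)
})

test_that("cluster event-time variance matches the temporal jitter", {
  # population sanity: delays drawn for 1e4 cells have the jitter variance
  set.seed(99)
  d <- rnorm(1e4, 3, 1)
  expect_lt(abs(var(d) - 1), 3 * sqrt(2 / (1e4 - 1)))  # 3 sd of var estimate
})

test_that("T + C assembly is linear with the correct delay", {
  ks <- cachedKernels()
  lfp_T <- reconvLfp(kernels = ks, seed = 3)
  zero <- new("LfpTrace", trace = numeric(length(lfp_T@trace)),
              dt = lfp_T@dt, onset_ms = lfp_T@onset_ms, provenance = list())
  expect_equal(assembleTC(lfp_T, zero)@trace[seq_along(lfp_T@trace)],
               lfp_T@trace)
  lfp_C <- reconvLfp(kernels = ks, seed = 4)
  tc <- assembleTC(lfp_T, lfp_C, delay_ms = 10)
  k <- round(10 / lfp_T@dt)
  expect_equal(tc@trace[k + seq_along(lfp_C@trace)],
               lfp_C@trace + c(lfp_T@trace[-seq_len(k)],
                               numeric(k))[seq_along(lfp_C@trace)])
  # two sink-view clusters: both waves negative
  m <- amplitudeAndLag(
    new("LfpTrace", trace = c(numeric(4000), tc@trace), dt = tc@dt,
        onset_ms = 100 + tc@onset_ms, provenance = list()))
  expect_equal(m$t_sign, -1)
})

test_that("sink and source view LFPs have opposite polarity", {
  pr <- stimulusProtocol("burst", rate_hz = 500, n_spikes = 3L, onset_ms = 10)
  ks_sink <- cachedKernels()
  ks_src <- generateKernelSet(representativeCombos(TRUE), seed = 11,
                              protocol = pr,
                              state = plasticityState(0.42, "normal"),
                              electrode = electrode("axon_bundle_source"))
  lfp_sink <- reconvLfp(kernels = ks_sink, seed = 3)
  lfp_src <- reconvLfp(kernels = ks_src, seed = 3)
  s1 <- lfp_sink@trace[which.max(abs(lfp_sink@trace))]
  s2 <- lfp_src@trace[which.max(abs(lfp_src@trace))]
  expect_lt(s1 * s2, 0)
})
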