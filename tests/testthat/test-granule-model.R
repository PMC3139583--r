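test_that("default morphology has 52 compartments in the documented groups", {
  cell <- cachedCell()
  cp <- cell@compartments
  expect_equal(nrow(cp), 52)
  expect_equal(sum(cp$group == "soma"), 1)
  expect_equal(sum(cp$group == "dendrite"), 16)
  expect_equal(sum(cp$group == "hillock"), 1)
  expect_equal(sum(cp$group == "axon"), 34)
  expect_equal(sum(cp$synaptic), 4)
  # Na concentrated at the hillock, far above dendrites
  d <- cell@channels$density
  expect_gt(d$gna[d$group == "hillock"], 10 * d$gna[d$group == "dendrite"])
})

test_that("invalid morphology graphs are rejected", {
  bad <- gcMorphology()
  bad$parent[5] <- 9L  # parent after child: cycle/forward reference
  expect_error(buildGranuleCell(list(morphology = bad)), "morphology|cycle")
  bad2 <- gcMorphology()
  bad2$L[3] <- -1
  expect_error(buildGranuleCell(list(morphology = bad2)), "positive")
})

test_that("an unstimulated cell settles at rest and conserves current", {
  cc <- simulateCell(cachedCell(), 200)
  v <- somaticVoltage(cc)
  n <- length(v)
  # settles within 0.5 mV of the resting value over the last half
  expect_lt(max(abs(v[(n / 2):n] - v[n])), 0.5)
  expect_lt(abs(v[n] - (-70)), 2)
  # Kirchhoff closure with no injection: total membrane current ~ 0
  expect_lt(max(abs(rowSums(membraneCurrents(cc)))), 1e-6)
})

test_that("current conservation holds under stimulation and synapses", {
  cc <- simulateCell(pulseCell(), 70, seed = 1)
  expect_lt(max(abs(rowSums(membraneCurrents(cc)) - cc@injected)), 1e-6)
  cc2 <- simulateCell(cachedCell(), 60,
                      stim = list(amp = 0.02, t0 = 10, t1 = 40))
  expect_lt(max(abs(rowSums(membraneCurrents(cc2)) - cc2@injected)), 1e-6)
})

test_that("rheobase is bracketed by spike/no-spike runs at +-1 pA", {
  cell <- cachedCell()
  rb <- rheobase(cell, tol_nA = 1e-3)
  run <- function(amp) length(spikeTimes(
    simulateCell(cell, 120, stim = list(amp = amp, t0 = 10, t1 = 110))))
  expect_gt(run(rb + 1e-3), 0)
  expect_equal(run(rb - 1e-3), 0)
  # granule-cell scale: a few pA to a few tens of pA
  expect_gt(rb, 0.001)
  expect_lt(rb, 0.05)
})

test_that("intrinsic excitability maps to the C_on/O_on scale pairs", {
  expect_equal(unname(ieScales("high")), c(0.20, 0.667))
  expect_equal(unname(ieScales("low")), c(2.0, 1.333))
  expect_equal(unname(ieScales("normal")), c(1, 1))
  cell <- cachedCell()
  expect_identical(setIntrinsicExcitability(cell, "normal")@channels,
                   cell@channels)
  # normal level leaves simulation output bit-identical
  c1 <- simulateCell(burstCell(), 60, seed = 3)
  c2 <- simulateCell(setIntrinsicExcitability(burstCell(), "normal"), 60,
                     seed = 3)
  expect_identical(somaticVoltage(c1), somaticVoltage(c2))
})

test_that("rheobase and spike count order with intrinsic excitability", {
  cell <- cachedCell()
  # deterministic bisection oracle at fine tolerance: the normal-vs-high
  # margin is small (the hillock Na reserve keeps threshold weakly
  # h-dependent on the high-excitability side) but strictly ordered
  rb <- sapply(c("low", "normal", "high"), function(lv)
    rheobase(setIntrinsicExcitability(cell, lv), tol_nA = 1e-5))
  expect_gt(rb["low"], rb["normal"])
  expect_gt(rb["normal"], rb["high"])
  spk <- sapply(c("low", "normal", "high"), function(lv)
    length(spikeTimes(simulateCell(burstCell(4, 4, p = 1, ie = lv), 60,
                                   seed = 5))))
  expect_true(spk["low"] <= spk["normal"])
  expect_true(spk["normal"] <= spk["high"])
})

test_that("attachSynapses places the requested synapses with 4 ms delay", {
  cell <- pulseCell(4, 4)
  expect_equal(nSynapses(cell), 8)
  inh <- grclfp:::.inhEvents(cell)
  expect_equal(min(inh$t), cell@protocol@onset_ms + 4)
  expect_equal(nSynapses(pulseCell(1, 0)), 1)
  # synapses sit on distinct dendritic tips
  expect_equal(anyDuplicated(cell@exc_comps), 0)
  expect_true(all(cell@compartments$synaptic[cell@exc_comps]))
})

test_that("p = 0 releases nothing and transfers no synaptic charge", {
  cell <- pulseCell(4, 0, p = 0)
  set.seed(1)
  expect_equal(nrow(sampleReleaseEvents(cell)), 0)
  expect_equal(synapticCharge(cell), 0)
})

test_that("release sampling follows p and shows paired-pulse depression", {
  cell <- burstCell(4, 0, p = 0.4)
  set.seed(123)
  n1 <- replicate(2000, {
    ev <- sampleReleaseEvents(cell)
    # quantal latency places first-pulse releases within ~1.5 ms of the pulse
    sum(ev$t < cell@protocol@onset_ms + 1.5)
  })
  # first-pulse releases are Binomial(4, p)
  expect_equal(mean(n1) / 4, 0.4, tolerance = 0.05)
  set.seed(123)
  rel <- replicate(2000, nrow(sampleReleaseEvents(cell)))
  # later pulses release less than p per synapse on average (depression)
  expect_lt(mean(rel), 3 * 4 * 0.4)
  expect_gt(mean(rel), 1.5 * 4 * 0.4)
})

test_that("inhibition gates the spike doublet and NMDA drives its 2nd spike", {
  with_inh <- simulateCell(pulseCell(4, 4), 70, seed = 1)
  expect_equal(length(spikeTimes(with_inh)), 1)
  no_inh <- simulateCell(pulseCell(4, 0), 70, seed = 1)
  expect_equal(length(spikeTimes(no_inh)), 2)
  # NMDA switch-off removes the doublet's second spike even without GABA
  cell <- pulseCell(4, 0)
  cell@synparams$nmda_scale <- 0
  expect_equal(length(spikeTimes(simulateCell(cell, 70, seed = 1))), 1)
})

test_that("peak spike Na current dwarfs the peak synaptic current", {
  cell <- pulseCell(4, 0)
  cc <- simulateCell(cell, 70, seed = 1)
  hil <- which(cell@compartments$group == "hillock")
  spike_peak <- max(abs(membraneCurrents(cc)[, hil]))
  # synaptic-only current: same release schedule with Na and KDR silenced
  passive <- buildGranuleCell(list(channels = list(density = data.frame(
    group = c("dendrite", "soma", "hillock", "axon"),
    gna = 0, gnap = 0, gkdr = 0, gl = 1 / 3000))))
  passive <- attachSynapses(passive, cell@protocol, cell@state)
  cp <- simulateCell(passive, 70, seed = 1)
  tips <- passive@compartments$synaptic
  syn_peak <- max(abs(rowSums(membraneCurrents(cp)[, tips])))
  expect_gt(spike_peak, 5 * syn_peak)
})

test_that("simulation reports divergence with a step location", {
  cell <- buildGranuleCell()
  expect_error(simulateCell(cell, 20, stim = list(amp = 50, t0 = 1, t1 = 19)),
               "diverged at step")
})

test_that("dt and duration preconditions are enforced", {
  expect_error(simulateCell(cachedCell(), 50, dt_ms = 0.05), "dt")
  expect_error(simulateCell(pulseCell(), 30), "50 ms")
})
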