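---
title: "Forward modeling and decomposition of granular-layer LFPs: methods"
author: "grclfp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forward modeling and decomposition of granular-layer LFPs: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grclfp)
```

## The problem

The evoked local field potential (LFP) of the cerebellar granular layer is an
ensemble signal: hundreds of granule cells near the electrode each contribute
a small extracellular current, and the recorded waveform mixes their synaptic
and spike currents with the temporal and spatial dispersion of the
population. `grclfp` implements a complete forward-and-inverse chain for this
signal:

1. a reduced multicompartment granule-cell model produces per-compartment
   transmembrane currents under mossy-fiber excitation and Golgi-like
   feed-forward inhibition;
2. the line-source approximation (LSA) converts those currents into the
   extracellular potential at an electrode — the single-cell *kernel*;
3. repetitive convolution (ReConv) synthesizes the population LFP from the
   kernels: temporal jitter of cell activation, weighting by the fraction of
   cells receiving 1–4 active mossy fibers, and spatial jitter of cell
   positions in the cluster;
4. blind source separation (JADE) plus cross-validated component-to-count
   mapping recovers those connectivity fractions from observed LFPs;
5. plasticity scenarios sweep release probability and intrinsic excitability
   to predict the LFP changes expressed by LTP and LTD.

Granule cells dominate the granular-layer field because their summed
electrogenic surface is about 30 times that of Golgi cells (a 500:1 count
ratio times a 3:50 single-cell surface ratio; `electrogenicSurfaceRatio()`),
so Golgi cells enter the model only as the inhibitory input train.

## The reduced granule cell

The full published granule-cell model this work descends from carries a dozen
ionic mechanisms. The downstream algorithms consume only the per-compartment
transmembrane currents, so the cell here is deliberately reduced to the
channels that shape those currents — transient Na (m³h), persistent Na,
delayed-rectifier K and leak — and *calibrated to a behavioral contract*
rather than to the donor model's waveforms:

* resting potential ≈ −70 mV with ~1 GΩ input resistance and a rheobase of a
  few pA (granule-cell scale);
* a single somatic spike in response to synchronous mossy-fiber input when
  feed-forward inhibition (arriving 4 ms later) is active, and a spike
  *doublet* when it is not;
* the second spike of the doublet is driven by the slow NMDA conductance and
  disappears when NMDA is blocked — the collision of NMDA-driven
  depolarization with GABA-A inhibition is what regulates doublet generation;
* the dominant extracellular sink during the spike is the axon hillock, where
  the Na density is set two orders of magnitude above the dendrites.

The morphology is the canonical 52-compartment layout: one soma, four
dendrites of four compartments each (the tips carry the synapses), an axon
hillock and a 34-compartment ascending axon. The axon is nearly passive in
this reduction: it serves as the distributed return path that makes an
electrode in the axon bundle see the *source* counterpart of the hillock
sink. Geometry is explicit (µm-scale cylinder end points) because the LSA
needs it.

### Intrinsic excitability (IE)

LTP and LTD express partly through non-synaptic excitability changes. These
are modeled, as in the donor tradition, by scaling the two pathways of Na
inactivation: the closed-state rate (C_on) and the open-state rate (O_on).
High IE scales (C_on, O_on) to (0.20, 0.667) of control; low IE to
(2.0, 1.333). In the reduced Hodgkin–Huxley h-gate this is realised by
splitting the inactivation-onset rate β_h into a closed-state component
weighted by (1 − m³) and an open-state component weighted by m³:

β_h(V, m) = β₀(V) · [C_on·(1 − m³) + O_on·m³]

Scaling C_on shifts the steady-state inactivation curve along the voltage
axis (the classical signature of these IE changes), which moves rheobase and
burst responsiveness in the right direction: rheobase(low) > rheobase(normal)
> rheobase(high).

### Synapses and release

Each active mossy fiber contributes one release site with a three-state
vesicle cycle: releasable → released (with probability *p* per presynaptic
spike) → recovering, with exponential refill (mean `tau_rec`, default 20 ms).
At 300–500 Hz this produces paired-pulse depression, and — more importantly
for the population statistics — makes the *total* release per burst saturate
in *p*: each site releases roughly once per burst however high *p* is. This
presynaptic saturation is what keeps the LFP's sensitivity to *p*
concentrated below the control point (p ≈ 0.4) and lets the intrinsic
excitability ladder restore bidirectional sensitivity, as the plasticity
sweeps show. Released quanta carry a small stochastic synaptic latency
(normal, mean 0.3 ms, sd 0.2 ms), the quantal latency variability of the
release machinery.

Conductance waveforms are double exponentials: fast AMPA (τ 0.3/1.2 ms),
slow NMDA (τ 6/18 ms) with the standard sigmoidal magnesium block at 1.2 mM,
and GABA-A (τ 0.5/12 ms, E = −75 mV) for the inhibitory synapses, which are
activated 4 ms after the mossy fibers (in vivo as a short burst of 3 IPSPs
at 100 Hz). Peak conductances (AMPA 0.313 nS, NMDA 0.65 nS, GABA-A 2.5 nS
per synapse) are calibration constants of the reduced model: they place the
coincidence threshold at about three near-simultaneous quanta, which is what
makes the naive active fraction land near 12.5% while disinhibition raises
it to ~50%. The h-gate kinetics are deliberately slow (recovery and onset
base rates 0.0512 and 1.6 ms⁻¹, preserving the steady-state curve): fast
coincidence spiking then samples the resting availability while slow
depolarizations sample the shifted steady state, which separates the
burst-response and threshold effects of the intrinsic-excitability scaling.

### Numerics

The cable equation on the dendro-somato-axonal tree is integrated with
backward Euler (unconditionally stable) and a Hines-ordered direct solve per
step; gating variables advance by Rush–Larsen exponential updates on the
previous-step voltage. The default step is 0.025 ms and larger steps are
refused. Before recording, the cell is relaxed to its true resting state for
150 ms at a coarse 0.5 ms step, so kernels have an exactly flat baseline.
Transmembrane currents are evaluated from the axial balance (net axial inflow
plus injected current), which makes the Kirchhoff closure — ΣᵢIₘ(i) equals
the injected current — hold to machine precision at every step; this is also
the quantity the LSA consumes (capacitive + ionic + synaptic). Integration
divergence (|V| > 200 mV) aborts with the step index.

## Extracellular forward model

The medium is homogeneous, isotropic and purely resistive. The granular-layer
default follows the field-potential literature's convention of quoting
resistivity as "0.1 MΩ/cm" — the resistance per unit length of a 1 cm²
column, i.e. 1e5 Ω·cm (`medium(0.1, unit = "MOhm/cm")`). This enters only as
a global amplitude scale; every shape- or ratio-based result (polarity,
percent changes, weight recovery) is independent of it, and absolute µV
values should be read with that convention in mind.

Each compartment is a finite line source; the potential is the standard
closed-form LSA integral, with the radial distance floored at 0.01 µm when
the electrode is nearly collinear with a segment (the regularized-log
branch). Superposition over compartments is exact, and for distances beyond
~20 segment lengths the LSA agrees with the point-source monopole to <1%.

Two electrode views are composed from the per-compartment potentials: the
granular-layer view sums dendrites + soma + hillock (spike sink, negative
deflection) and the axon-bundle view sums the axonal compartments (return
source, positive deflection). The electrode sits 10 µm lateral to the soma
by default (the cluster-center position of the spatial convolution); the
source-view default is alongside the axon at z = −60 µm. These defaults are
package choices — the source publications of this modeling tradition do not
fix electrode coordinates.

## Repetitive convolution

The population LFP is assembled in the five canonical steps: (1) single-cell
kernels per input combination — with 1–4 mossy fibers and 0–4 inhibitory
inputs there are 20 combinations, of which the complementary pairings 1/4,
2/3, 3/2, 4/1 are the representative set; (2) convolution with the temporal
jitter of cell activation (normal, mean 3 ms, sd 1 ms — the presynaptic
neurotransmission delay); (3) weighting by the connectivity fractions w₁..w₄
(in vivo 15/35/35/15%, in vitro 5/45/35/15%); (4) spatial jitter: cell
positions uniform in a 15 µm-radius sphere around the electrode, each cell's
contribution scaled by the point-source attenuation r₀/max(r, 1 µm) relative
to the kernel's reference distance r₀; (5) the weighted sum over the
cluster — ~220 cells for the in vivo LFP, ~600 in vitro. The T and C waves
are built from two independent clusters, with C delayed 10 ms and inhibition
drawn independently per cluster.

Step (3)'s weights are the connectivity fractions and step (5)'s weights are
the distance attenuations; this is the only reading consistent with both the
published weight table and the sphere geometry. The uniform-in-volume
position density and the 1 µm floor are package choices, configurable through
`jitterSpec()` and documented here.

The plasticity scenarios (`runState()`) use a per-cell Monte-Carlo variant of
the same chain: every cluster cell is an independent stochastic realization
(its own mossy-fiber count, release samples, latency and position), which is
what makes a per-cluster *active fraction* — the percentage of cells firing
at least one spike — well defined. The in vivo mossy-fiber input is a short
high-frequency burst (5 spikes at 500 Hz by default, within the 300–500 Hz /
"short train" envelope of the tradition; the rate, count and single-pulse in
vitro mode are all protocol presets).

## Blind source separation and weight recovery

JADE is implemented from its standard definition: time-centering, PCA
whitening to the four leading directions, the parallel set of fourth-order
cumulant matrices, and joint diagonalization by Givens rotations with the
closed-form angle. Rank deficiency after whitening raises an error;
components with no excess kurtosis are flagged (`reliable = FALSE`), since
ICA cannot separate Gaussian sources.

Components are mapped to mossy-fiber counts by generate-and-compare: the
ReConv engine regenerates the per-count candidate fields, each of the 24
assignments is scored by the scale-matched, mean-free waveform MSE between
component and candidate over the window from stimulus onset to +50 ms (the
window is a documented package default), and the best assignment is kept,
with exact ties reported as such. Because the four candidate fields are
mutually correlated waveforms, the mixing matrix cannot be read as weights
directly; connectivity fractions are instead estimated per trace by
non-negative projection onto the candidate fields and averaged, with min–max
ranges reported. The cross-validated MSE repeats this under `n = 10` random
2-fold splits: weights fitted on the training fold regenerate an LFP whose
relative waveform error is scored on the held-out traces.

Weight estimation assumes a uniform release probability p = 0.42 (the value
measured in vitro), encoded in the kernel set used for regeneration.

## The synthetic-data generator

`generateFixture()` emulates a set of in-vivo-like evoked LFP recordings for
closed-loop testing: each observation is a ReConv LFP whose weights are the
true weights perturbed multiplicatively (sd 10% relative — different
recording sites sample slightly different clusters), plus additive Gaussian
noise with sd 0.5 µV representing the residual after the usual 10–16-trace
averaging. Fourteen traces are generated by default, the size of a typical
in vivo data set. The generator records its ground truth, so recovery can be
scored exactly.

What the fixtures do *not* emulate: electrode drift, non-stationary
background rhythms, Golgi-cell spike contamination, animal-to-animal
variability of kernel shape, or correlated noise across traces. Passing the
closed-loop tests therefore demonstrates the *self-consistency* of the
decomposition — that the pipeline recovers what the forward model generated —
not performance on arbitrary experimental recordings.

## Measurement conventions

Wave amplitudes are measured at the peak relative to the mean of the 100 ms
window preceding stimulation, as magnitudes of the largest
baseline-subtracted deflection; the T peak is searched within 10 ms of
stimulus onset and the C peak between the 10 ms cortico-ponto-cerebellar
delay and +35 ms. The T lag is onset-to-peak time; a flat trace yields zero
amplitudes and an NA-flagged lag. Simulated LFP measurements are taken on
15-repetition averages after 2 kHz zero-phase low-pass filtering, mirroring
the processing of experimental traces; the 100 Hz high-pass that stabilises
recording baselines is unnecessary for model traces (their baseline is
exactly flat) and is not applied to them. Filters are zero-phase Butterworth
(order 2 per pass), the standard evoked-potential choice; the family and
order are package decisions exposed in `filterSpec()`.

## Problem sizes and determinism

The package's own test and reproduction runs use the study-scale conditions:
220-cell clusters, 15-repetition averages for the in vivo scenarios and the
plasticity states, 14-trace fixture sets with 2-fold × 10 cross-validation
for the weight recovery. Property-style unit tests run reduced clusters
(20–60 cells, 2–3 repetitions) because the per-cell spiking statistics, not
the cluster size, carry the tested contracts. All randomness flows through
R's RNG: a fixed seed reproduces every trace bit-for-bit, including release
sampling, jitter draws and fixture noise.

## Known limitations

* The reduced channel set reproduces the behavioral contract, not the donor
  model's voltage waveforms; slow Na inactivation is deliberately excluded.
* The LTP/LTD expression states (Δp = ±0.2 with the concurrent IE step)
  reproduce the direction and ordering of the active-fraction and amplitude
  changes, but not all magnitudes: the quantal-coincidence threshold that
  yields the correct naive (~12.5%) and disinhibited (~50%) fractions is
  steep in p, so the LTP-state fraction and the T/C amplitude changes
  overshoot the reference values and the LTD-state fraction undershoots.
  The T/C peak at the default electrode is spike-dominated (the subthreshold
  synaptic field appears with opposite sign there), which further amplifies
  state-to-state amplitude changes relative to a model with a larger
  synaptic share.
* Golgi cells are input trains, not modeled neurons; network effects
  (lateral inhibition, gap junctions, center–surround) are out of scope.
* The medium is homogeneous and frequency-independent; no current-source
  density inversion is attempted.
* One cell model stands for all cells (clusters are homogeneous apart from
  the stochastic realization), matching the mean-field character of the
  approach.
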