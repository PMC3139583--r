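Package: grclfp
Title: Forward Modeling and Decomposition of Cerebellar Granular-Layer Local Field Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Biophysical forward model of the local field potential (LFP)
    generated by clusters of cerebellar granule cells. A reduced
    multicompartment granule-cell model (transient and persistent Na,
    delayed-rectifier K, leak; stochastic three-state vesicle release;
    GABA-A feed-forward inhibition) produces per-compartment transmembrane
    currents, converted to extracellular single-cell kernels with the
    line-source approximation in a resistive medium. Population LFPs are
    synthesized by repetitive convolution over mossy-fiber input combinations
    with temporal and spatial jitter, decomposed by JADE blind source
    separation with cross-validated mapping of components to mossy-fiber
    counts, and used to predict LFP changes under long-term plasticity of
    release probability and intrinsic excitability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    signal
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
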