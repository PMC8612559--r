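Package: egabathr
Title: Spatiotemporal Determinants of Depolarizing GABAergic Excitation in
    Compartmental Neuron Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Compartmental cable models of immature hippocampal pyramidal
    neurons with a cooperative (modified Naundorf) sodium spike mechanism,
    conductance-based GABA-A and AMPA synapses, tonic GABAergic conductances,
    and the iterative conductance-threshold machinery needed to locate the
    GABA reversal potential at which depolarizing GABAergic input switches
    from inhibitory to excitatory (the threshold E_GABA). Includes four
    action-potential threshold estimators, rheobase searches, reciprocal and
    intersection estimators of threshold E_GABA, delay/spatial/tonic scans,
    stochastic synaptic-bombardment spike-probability experiments on seeded
    synthetic branched morphologies, and Goldman-Hodgkin-Katz conversion
    between E_GABA and intracellular chloride.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
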