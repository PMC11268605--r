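Package: nervesim
Title: Simulation of Electrical Stimulation and Recording of Peripheral Nerve Fibers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Self-contained simulator for electrical stimulation and recording of
    peripheral-nerve fibers. Analytic extracellular potentials from point-source
    electrodes in infinite homogeneous (an)isotropic media drive conductance-based
    compartmental axon models: unmyelinated Hodgkin-Huxley fibers and myelinated
    double-cable fibers with nodal fast/persistent sodium and slow potassium
    channels. Includes fiber population generation and packing into fascicles,
    analytic point- and line-source compound action potential (eCAP) recording,
    activation and kilohertz-block threshold searches, recruitment-curve and
    amplitude-latency analyses, and a generic particle-swarm stimulation-waveform
    optimization layer.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    parallel
Config/testthat/edition: 3
SystemRequirements: C++17
RoxygenNote: 7.3.3
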