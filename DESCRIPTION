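Package: GqSpine
Title: Stochastic Reaction-Diffusion Modeling of Gq-Coupled Signaling in
    Dendritic Spines
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Mesoscopic stochastic reaction-diffusion (spatial tau-leap)
    simulation of the Gq-coupled signaling network controlling
    endocannabinoid (2-arachidonoylglycerol) production and protein kinase C
    activation in striatal medium spiny neuron dendrites and spines.
    Provides the full mass-action reaction network with calcium buffers,
    pumps, metabotropic glutamate receptor/G-protein cycle, phospholipase
    C beta, diacylglycerol lipase and PKC; compartmental dendrite/spine
    meshes; depolarization (DSI), theta-burst and 20 Hz stimulation
    protocols; trajectory analysis (regional concentrations, enhancement
    ratios, PKC:2AG plasticity index); and experiment suites for
    dose-response validation, temporal-pattern discrimination, spatial
    specificity and parameter-robustness studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    deSolve
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
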