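Package: dentatestdp
Title: Voltage-Based STDP with Fast BCM-Like Metaplasticity in a
    Compartmental Dentate Granule Cell
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-loop simulation of homosynaptic long-term potentiation
    (LTP) and concurrent heterosynaptic long-term depression (LTD) at the
    medial and lateral perforant path inputs of a reduced-morphology
    multicompartment dentate gyrus granule cell.  Synaptic weights evolve
    under a presynaptically centered nearest-neighbour spike-timing-dependent
    plasticity (STDP) rule in which the postsynaptic event is a local
    dendritic voltage threshold crossing, combined with a fast
    Bienenstock-Cooper-Munro (BCM)-like homeostatic scaling of the
    potentiation and depression amplitudes driven by the running average of
    somatic spiking.  Includes quasi-periodic afferent spike-train
    generators, delta-burst and theta-burst high-frequency stimulation
    protocols, an implicit cable-equation integrator with
    Hodgkin-Huxley-style membrane mechanisms, channel-block experiments,
    a scenario registry, and tidy result containers with ggplot2 methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
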