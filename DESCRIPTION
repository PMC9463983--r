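Package: ca1plast
Title: Cholinergic and Disinhibition-Gated Plasticity in a CA1 Microcircuit Model
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Biophysical simulation of a minimal hippocampal feedforward
    disinhibition circuit: an oriens-lacunosum-moleculare (OLM) interneuron,
    a fast-spiking interneuron, and a passive CA1 pyramidal dendritic
    compartment coupled by kinetic AMPA, NMDA, GABA-A and alpha7 nicotinic
    receptor models. Includes calcium-induced calcium release at the OLM
    GABAergic terminal, a calcium-based AMPA receptor plasticity rule, the
    stimulation protocols used to study cholinergic copairing and
    disinhibition-driven potentiation at the Schaffer collateral-CA1 synapse
    (pairing-window scans, disinhibition endpoints, GABA-timing phase maps),
    and analysis utilities (EPSC normalization, learning-rate-weighted
    calcium area ratio, plasticity-window boundary extraction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
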