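Package: metaspheroid
Title: Hybrid Multiscale Simulation of Tumor Spheroid Metabolism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of multicellular tumor spheroids coupled
    to a reaction-diffusion microenvironment (oxygen, glucose, lactate,
    protons) and a per-cell gene-metabolism network with pH-regulated
    glycolysis and reversible lactate-proton symport. Provides the multirate
    scheduler binding the three scales, cell-cycle and necrosis models,
    metabolic phenotype classifiers (fermentative/respiratory, Warburg and
    reverse-Warburg lactate status), LDH-PDH metabolic-landscape analysis,
    and ready-made perturbation scenarios (cyclic hypoxia, acid shock,
    glucose depletion, glycolytic challenge).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
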