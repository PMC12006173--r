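Package: spinekin
Title: Stochastic Simulation of CaMKII Autophosphorylation and CaM-Trapping in a Dendritic Spine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale stochastic simulator of the Ca2+/calmodulin/CaMKII/PP1
    signaling network in a median-sized dendritic spine. Couples a synthetic
    two-epoch presynaptic stimulus (stochastic vesicle release, coincidence-gated
    NMDAR Ca2+ influx) to a well-mixed compartmental chemistry engine: nine-species
    calmodulin Ca2+ binding in three binding contexts, dodecameric CaMKII
    holoenzymes with directional intra-ring Thr286 autophosphorylation,
    CaM-trapping (low- to high-affinity transition of the CaM site), and
    Michaelis-Menten dephosphorylation by protein phosphatase 1 with an optional
    steric CaM-block rule. All context-dependent rate constants are derived from
    thermodynamic detailed balance. Includes an exact Gillespie engine and a
    faster hybrid tau-leaping mode, ensemble summaries, exponential decay-constant
    fitting, and PSD-capsule localization variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
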