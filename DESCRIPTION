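Package: cyanoflux
Title: Constraint-Based Analysis of Cyanobacterial Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux balance analysis (FBA) and flux variability analysis (FVA)
    for compartmented genome-scale metabolic models of cyanobacteria, with
    diurnal (light/dark) regulatory constraints, gene-protein-reaction (GPR)
    Boolean logic for in silico knockouts, single-gene-deletion essentiality
    screening against in vivo viability data, and model quality control:
    elemental/charge balance linting, blocked-metabolite detection, minimal
    gap-fill proposals, and detection of thermodynamically infeasible loops.
    Reads and writes SBML (Level 3 with the fbc package, plus legacy Level 2
    flux-bound encodings) and ships a synthetic-network generator with known
    ground truth so every analysis stage is testable without external model
    files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
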