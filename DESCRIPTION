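Package: poloplan
Title: Direct Optimization of the Probability of Lesion Origin in Proton
    Treatment Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise outcome-model-based optimization of intensity-modulated
    proton treatment plans for low-grade glioma. Implements the probability of
    lesion origin (POLO) logistic model on dose, dose-averaged linear energy
    transfer and ventricular proximity, its volume-corrected extension and
    linear reformulation, analytic backward differentiation from model output
    to beamlet fluence, four model-based scalar objectives (serial-tissue NTCP,
    log-sum-exp, and Hellinger-type mean reductions on the probability and
    decision scales), conventional dose-volume objectives and box dose
    constraints, and a constrained weighted-sum fluence optimizer. Ships a
    synthetic voxelized brain phantom generator and a simplified analytic
    pencil-beam influence model (Bragg-like depth-dose, distal LET elevation)
    so the full pipeline runs without clinical data, plus plan evaluation
    (DVH, LET-volume histograms, D95, POLO histograms, NTCP iteration traces).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
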