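Package: bbbPK
Title: Blood-Brain Barrier Transport Pharmacokinetics from In Situ Brain Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of dual-isotope in situ brain perfusion experiments at
    the blood-brain barrier: vascular-space correction with a non-penetrating
    marker, initial transport clearance (Kin), capillary extraction against a
    flow marker with a flow-independence rule, and group inference
    (mean +/- SD, Student t, one-way ANOVA with Tukey HSD, bootstrap
    confidence intervals on fold changes of group means). Includes a
    mechanistic Crone-Renkin simulator of perfusion studies with known ground
    truth (passive permeability, saturable ABC-transporter efflux, inhibitor
    and knockout effects, biological and counting noise) for parameter
    recovery testing, and an isotope-dilution targeted-proteomics
    quantification step (calibration curve fitting, limit-of-quantification
    flagging, absolute transporter concentrations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
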