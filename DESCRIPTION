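Package: pepfunnel
Title: Staged In Silico Screening of Food-Derived DPP-IV-Inhibitory Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for post-processing peptidomics peptide pools into
    candidate dipeptidyl peptidase IV (DPP-IV) inhibitory peptides. Provides
    a cleavage-rule simulator for gastrointestinal (gastric then intestinal)
    in silico digestion of protein sequences, exact-match lookup against a
    bundled known-bioactive-peptide reference table, a staged screening
    funnel (bioactivity-rank filter, active-site-binding p-value filter,
    novelty partition, structure-activity-relationship selection), a
    rule-based SAR engine encoding the positional residue features of potent
    DPP-IV inhibitors, and Hill-model dose-response simulation and IC50
    estimation for in vitro validation data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
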