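Package: pkdscreen
Title: Quantitative High-Throughput Screening Triage for ADPKD Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative high-throughput viability
    screens (qHTS) aimed at repurposing compounds for autosomal dominant
    polycystic kidney disease (ADPKD). Provides plate-wise normalization to
    intra-plate controls with Z-prime quality metrics, four-parameter Hill
    curve fitting with a signed curve-class taxonomy, area-under-curve (AUC)
    summaries, differential hit calling between paired Pkd1-null and
    wild-type mouse lines and between patient-derived ADPKD and normal human
    kidney (NHK) isolates, activity calling for 3D cyst assays, image-based
    cyst quantification from bright-field z-stacks, paired Wilcoxon
    panel-similarity matrices, and primary-target enrichment with
    Benjamini-Hochberg correction. A synthetic-screen generator with planted
    ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
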