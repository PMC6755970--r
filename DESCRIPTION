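Package: seedscreen
Title: Plate B-Score Screening, miRNA Seed-Site Scanning and Reporter
    Quantification for AR-Activity miRNA Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for microRNA-inhibitor reporter screens of
    androgen receptor (AR) activity in prostate cancer cell lines. Computes
    per-well B scores via Tukey two-way median polish of 96-well plates,
    calls and compares hits across cell lines, scans arbitrary-length
    3'UTRs for canonical miRNA seed-complementarity sites (6mer, 7mer-A1,
    7mer-m8, 8mer), designs seed-disrupting mutants, and quantifies
    companion assays: luciferase/beta-galactosidase reporter normalisation,
    2^-ddCt relative expression, RNA-IP percent-of-input, transcript
    stability after transcriptional block, day-0-relative growth curves,
    and a z-score-based AR pathway activity score with linear-regression
    association. Ships a synthetic-data generator with known ground truth
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
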