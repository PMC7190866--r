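Package: isoscreen
Title: Isogenic Cell-Line Panel Drug-Screen Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for high-throughput drug screens run on
    isogenic cell-line panels. Normalizes plate-reader luminescence to
    DMSO-relative inhibition scores, calls efficacious and line-selective
    compounds, clusters inhibition profiles, fits four-parameter logistic
    dose-response curves with IC50/ED50 extraction and potency fold-change
    comparison, scores drug-combination dose matrices under the Bliss
    independence model, and annotates direct transcription-factor target
    genes by intersecting ChIP peaks proximal to transcription start sites
    with differentially expressed genes. Includes a seeded synthetic-data
    generator emulating a three-line screen with planted ground truth so
    the whole pipeline is testable end to end without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
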