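Package: ledar
Title: Linear Equation of Deconvolution Analysis for Co-Eluting Isomers in
    Ion-Trap LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recognizes and quantifies co-eluting isomers from ion-trap
    LC-MS/MS runs acquired with alternating low-energy (reference-ion) and
    high-energy (product-ion) MS/MS events.  Implements energy-resolved MS/MS
    (ERMS) breakdown-curve analysis (survival yield, product-ion formation and
    product-ion yield curves with their CID summary statistics), characteristic
    product-to-reference ion ratio tables, overdetermined non-negative linear
    deconvolution of mixed MS/MS signals per scan and per integrated peak,
    reconstruction of per-isomer chromatographic traces from unresolved peaks,
    and external-standard quantification with SE-based LOD/LOQ estimation.
    Includes seedable generators of synthetic LC-MS/MS runs and ERMS series so
    the whole pipeline is testable without instrument data, plus a small
    command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    pracma,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
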