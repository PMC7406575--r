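Package: pelprofiler
Title: Product-Profile Fingerprinting of Pectin Lyase Digests from LC-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discriminative substrate degradation profiling of
    pectin lyases (EC 4.2.2.10). Implements a compositional mass and adduct
    m/z model for methyl- and acetyl-substituted unsaturated
    oligogalacturonides, Domon-Costello fragment prediction with acetyl
    localization, peak-to-compound identification, max-normalized product
    profile fingerprinting with complete-linkage hierarchical clustering,
    a subsite-rule Gillespie simulator of homogalacturonan beta-elimination
    that generates synthetic LC-MS-like peak tables, and small enzymology
    helpers (DM/DAc, bond concentration, A235 rates, Hanes-Woolf kinetics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    jsonlite
Config/testthat/edition: 3
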