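Package: mrmassay
Title: Design and Label-Free Quantification of Multiple Reaction
    Monitoring Assays for Bacterial Secreted Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building targeted proteomics (multiple reaction
    monitoring, MRM) assays for bacterial proteins and for label-free
    quantification from the resulting chromatograms. Covers in-silico
    tryptic digestion with proteotypic-peptide filtering, monoisotopic
    precursor and b/y fragment-ion m/z calculation, linear collision-energy
    and declustering-potential models, transition-list export, Gaussian
    chromatogram simulation for method validation, peak detection and
    integration, calibration curves with linear-range and lower limit of
    quantification estimation, and strain-comparison reporting of secreted
    protease concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
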