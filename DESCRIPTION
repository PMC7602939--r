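Package: mscurate
Title: QC-Driven Curation and Raw-Data Processing for LC-MS Untargeted Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for preprocessing liquid chromatography-mass spectrometry
    (LC-MS) untargeted metabolomics experiments. Reads centroid mzML runs,
    builds extracted ion chromatograms and accumulated spectra, detects
    chromatographic peaks with a continuous wavelet transform (Ricker wavelet,
    ridge-line selection) and features with a centWave-style region-of-interest
    procedure, and matches features across samples by density-based clustering
    in (m/z, retention time) space. Curates the resulting sample-by-feature
    area matrix with a pooled-QC-based pipeline: retention-time and
    QC-presence filters, blank correction, per-feature LOESS signal-drift
    correction with leave-one-out cross-validated span selection, robust-RSD,
    prevalence and D-ratio filters, and total-area normalization, with a
    per-step removal log. Includes system-suitability checking against
    replicate standard injections, PCA-based quality assessment, and seeded
    synthetic-data generators for raw runs and study matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mzR,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
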