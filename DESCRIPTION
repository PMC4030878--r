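Package: SpectraQuant
Title: Multi-Color Spectral Transcript Analysis for Fluorescence Image Cubes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative multi-color fluorescence in situ
    hybridization read out by Fourier-transform spectral imaging. Simulates
    fields of fluorescent calibration beads and two-population cell mixtures
    with known ground truth, forward-models Sagnac interferograms and
    reconstructs spectral image cubes, performs linear spectral un-mixing of
    per-pixel emission spectra against reference dye libraries (up to nine
    fluorochromes plus background), segments cells from DAPI reference images
    or by seeded region growing, and quantifies per-cell reporter levels for
    population classification and rare-cell detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    png,
    jsonlite,
    pracma,
    EBImage
Suggests:
    testthat (>= 3.0.0)
biocViews: Software, CellBiology, Visualization, Transcriptomics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
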