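Package: spaMSI
Title: Integration of Spatial Transcriptomics and Mass Spectrometry Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating same-section MALDI mass spectrometry imaging
    (MSI) metabolomics with Visium-style spatially resolved transcriptomics (SRT).
    Provides readers for Visium-layout count directories, peak-table CSVs and
    continuous-mode imzML; spot and gene quality-control filters; landmark-based
    similarity registration of the MSI raster into the histology pixel frame;
    cross-modality nearest-neighbour pairing of MSI pixels to RNA spots;
    metabolite-gene Pearson correlation screens with Benjamini-Hochberg FDR
    control; joint PCA co-embedding with cosine-kNN peak-gene graph construction
    and spinglass community detection; and a synthetic paired-data generator with
    known ground truth for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    vegan,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'crossmodal.R'
    'io.R'
    'modules.R'
    'msi-preprocess.R'
    'pipeline.R'
    'registration.R'
    'spaMSI-package.R'
    'srt-preprocess.R'
    'synthetic.R'
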