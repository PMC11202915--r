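Package: porkHSI
Title: Hyperspectral Imaging Pipeline for Staging Pork During Postmortem
    Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stages pork as rigor-mortis, aged or spoiled from visible/short-NIR
    hyperspectral reflectance cubes. Implements ENVI cube input/output,
    histogram (Otsu) background segmentation, mean region-of-interest and
    per-pixel spectrum extraction, multilevel discrete wavelet transform
    feature extraction over seven mother wavelets, a particle-swarm-optimised
    radial-basis support vector machine stage classifier, pixel-wise
    pseudo-colour aging maps, and the physicochemical freshness indices
    (myofibrillar fragmentation index, total volatile basic nitrogen, total
    viable count) with the storage-stage labelling rules built on them. A
    synthetic-data module generates class-structured spectra, hypercubes with
    edge-first aging geometry and per-day physicochemical trajectories so the
    whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    png,
    jsonlite,
    S4Vectors,
    SummarizedExperiment,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Classification, Spectroscopy, Preprocessing
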