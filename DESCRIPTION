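Package: spatmsi
Title: Geostatistical Simulation and Clustering Benchmarks for Mass
    Spectrometry Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates spatially autocorrelated, cluster-structured
    intensity cubes that mimic mass spectrometry imaging (MSI) data
    (per-cluster spherical variograms, geometric anisotropy, cluster-wise
    spectral correlation, normal / Fleishman non-normal / bimodal
    marginals), and benchmarks segmentation pipelines on them: k-means
    with Euclidean or correlation distance, Gaussian mixture models,
    a spatially-aware k-means variant, combined with PCA, spatial PCA,
    minimum noise fraction and t-SNE front-ends, scored by the adjusted
    Rand index. Also provides an MSI preprocessing pipeline (0.1 Da
    binning with local-maxima peak picking, matrix-peak removal, TIC
    normalization, per-image median filtering) and internal cluster
    validity indices (Calinski-Harabasz, Davies-Bouldin) with k
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    pracma
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, MassSpectrometry, ImagingMassSpectrometry,
    Clustering, DimensionReduction, Spatial
RoxygenNote: 7.3.3
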