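# spatmsi

Ground-truth benchmarking for mass spectrometry imaging (MSI) segmentation.

MSI produces an `x × y × m/z` intensity cube — one mass spectrum per pixel
of a tissue section — and unsupervised clustering of pixels is the standard
way to extract spatially coherent regions from it. Real MSI data, however,
provide no ground truth against which to score a clustering pipeline.
`spatmsi` fills that gap for analysts and method developers:

* a **geostatistical simulator** that generates MSI-like intensity cubes
  with *known* cluster labels, reproducing the statistical features that
  make the problem hard: per-cluster spherical variograms
  (`C(h) = b(1 − 3/2·h/a + 1/2·(h/a)³)` for `h ≤ a`, 0 beyond; range `a`,
  sill `b`), geometric anisotropy (`c* = c(RT)⁻¹`, rotation 45°, axis
  scales 1/0.5), cluster-wise spectral correlation in [0.4, 0.7] imposed
  by Cholesky factors, and normal / Fleishman non-normal / bimodal
  marginals, plus mean-shift and noise-variable scenarios;
* the **clustering methods** most used on MSI data — k-means with
  Euclidean or correlation (1 − Pearson) distance, Gaussian-mixture EM
  (spherical / diagonal / full / BIC-auto), and a spatially-aware k-means
  on Gaussian-weighted neighborhood spectra;
* the **dimension-reduction front-ends** they are paired with — PCA (4
  components), spatial PCA (4 components, lag-5 spatial weights), minimum
  noise fraction (6 components, shift-difference noise estimate), and a
  t-SNE adapter (2 dimensions, perplexity 10, on 10 PCA dimensions);
* **validation**: adjusted Rand index against the ground truth, plus
  Calinski–Harabasz / Davies–Bouldin internal indices with k selection;
* an **MSI preprocessing pipeline** (0.1 Da binning with local-maxima
  peak picking, off-tissue matrix-peak removal, TIC normalization,
  per-ion-image median filtering) for bridging from real spectra.

The methods vignette (`vignettes/spatmsi-methods.Rmd`) documents the
generative model, every tunable parameter, and the design decisions.

## Worked example

Simulate the hardest two-cluster condition (spatial type 3: ranges 20/10,
sills 0.1/0.3; mixed marginals; 10 mean-shifted variables per cluster) at
reduced 40 × 40 size, then compare GMM on raw data against GMM on MNF
scores:

```r
library(spatmsi)

spec <- scenarioSpec(spatial_type = 3,
                     distribution = distributionSpec("mixed"),
                     mean_mod = "VarMod_10_10",
                     grid_dim = c(40, 40), seed = 7)
cube <- simulateScenario(spec)
cube
#> class: MsiSimCube
#> dim: 100 1600
#> metadata(3): scenario modified_vars noise_vars
#> assays(1): intensity
#> rownames(100): V1 V2 ... V99 V100
#> rowData names(0):
#> colnames(1600): px1 px2 ... px1599 px1600
#> colData names(3): x y truth

raw <- gmmEM(intensityMatrix(cube), k = 2, "auto", seed = 1)
adjustedRandIndex(clusterLabels(raw), truthLabels(cube))
#> [1] 1

mnf <- mnfReduce(cube, n_components = 6)
red <- gmmEM(reducedScores(mnf), k = 2, "auto", seed = 1)
adjustedRandIndex(clusterLabels(red), truthLabels(cube))
#> [1] 0.9900188
```

ARI is 1 for a perfect partition and ≈ 0 for a random one. The benchmark
driver crosses scenarios × methods × front-ends with paired seeds and
aggregates median ARI:

```r
tab <- runStudy(list(spec), methods = c("gmm", "kmeans_euclidean"),
                dimreds = c("raw", "mnf"), reps = 3, master_seed = 1)
summarizeMedianAri(tab)
#>                      scenario           method dimred median_ari n_reps
#> 1 type3_mixed_VarMod_10_10_k2              gmm    mnf  0.9900188      3
#> 3 type3_mixed_VarMod_10_10_k2              gmm    raw  1.0000000      3
#> 2 type3_mixed_VarMod_10_10_k2 kmeans_euclidean    mnf  0.9825657      3
#> 4 type3_mixed_VarMod_10_10_k2 kmeans_euclidean    raw  0.7786697      3
```

On this hardest condition the BIC-selected full-covariance mixture
separates the clusters even in the raw 100-dimensional space, while
Euclidean k-means — blind to covariance structure — recovers only part of
the segmentation on raw data (median ARI 0.78) and is lifted to 0.98 when
the minimum-noise-fraction transform concentrates the spatially smooth
signal into six components. Mean-zero scenarios (`mean_mod = "VarMod_0"`)
strip the mean contrast away and widen the method differences further.

A thin command-line wrapper for the simulate / bench / report / cluster /
preprocess steps ships in `inst/scripts/spatmsi-cli.R`.

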