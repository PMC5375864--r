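Package: shadespec
Title: Sunlit and Shaded Canopy Component Analysis for Near-Ground Imaging Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing near-ground hyperspectral images of crop
    canopies in which sunlit and shaded leaves and panicles must be separated
    before chlorophyll estimation. Implements radiometric calibration from
    digital numbers, minimum noise fraction denoising, band subsetting and
    EVI-based vegetation masking; continuum removal by upper convex hull;
    the NDVI, TCARI, PRI, red-edge chlorophyll index and EVI vegetation
    indices; spectral angle mapper and spectral information divergence
    matching against class mean spectra; a PRI/TCARI decision tree with
    data-derived thresholds and ten-fold cross-validation; and
    SPAD-to-chlorophyll bookkeeping with sunlit-versus-shaded regression
    comparisons (Spearman correlation, linear and exponential fits on
    z-scored indices). A synthetic-scene generator produces labelled
    hyperspectral cubes and plot-level agronomic truth with the qualitative
    spectral structure of rice canopies, so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
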