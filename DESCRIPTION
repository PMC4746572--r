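Package: mtpscore
Title: Tile-Based Dual-Channel Immunofluorescence Quantification and
    HER2 Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies membrane-marker expression on multichannel
    fluorescence tile mosaics of tissue sections. Each tile is reduced to
    an epithelial, non-nuclear region of interest by Otsu auto-thresholding
    of the cytokeratin (CK) channel with DAPI nuclear exclusion; tile-wise
    HER2/CK ratios are filtered case by case, histogrammed, and summarised
    by a Gaussian fit whose mean and width - normalised by an IHC 3+
    positive control in the same batch - yield the M-, Sigma- and
    MTP-scores. Cohort-level tools correlate scores against FISH gene copy
    number with power-law fits and flag intratumoural heterogeneity by
    Gaussian-mixture comparison. A seeded synthetic-mosaic generator
    provides ground truth for every stage, and a Langmuir binding-kinetics
    module models the short-incubation linearity of antibody recognition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    mclust,
    minpack.lm,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
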