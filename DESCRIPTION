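Package: phenoMaize
Title: Phenology-Based Maize Cropland Mapping from Multispectral Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for mapping maize cropland
    from six-band optical satellite time series: seed-controlled simulation of
    Landsat-like scene stacks with crop phenology, cloud contamination and
    parcel structure; cloud filtering and gap-filling followed by two-month
    maximum-value compositing into a 4-period x 6-band feature sequence; a
    three-layer LSTM classifier with a fully connected head trained by
    cross-entropy plus weighted center loss (implemented natively, including
    backpropagation through time and Adam); cropland masking and minimum
    mapping unit speckle removal; and thematic-map validation (confusion
    matrices, user's/producer's accuracy, F1, overall accuracy) together with
    region-level area consistency checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
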