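Package: thalaquant
Title: Quantification Pipeline for Thalamic Neurodegeneration Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for a mouse model study of thalamic
    neurodegeneration: calibrated ex vivo autoradiogram quantification
    (standardized uptake values with radioactive decay correction and
    reference-region ratios), current-clamp intrinsic-property extraction
    (passive membrane properties, action-potential waveform features,
    frequency-current curves, rebound bursts), dendritic morphometry from
    SWC reconstructions with shrinkage correction, immunofluorescence cell
    counting and immunoreactive-area fractions, open-field trajectory
    metrics, and group statistics including a summary-statistics one-way
    ANOVA reconstructor. Synthetic-data generators with known ground truth
    (phantom autoradiograms, an adaptive exponential integrate-and-fire
    neuron simulator with low-threshold rebound bursting, disk-cell
    fluorescence fields, arena trajectories, toy dendritic trees) make the
    whole pipeline testable without raw images or recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    tiff,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
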