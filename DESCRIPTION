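Package: mseeg
Title: Multi-Site EEG Harmonization, Cleaning Provenance and Cluster Statistics
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for standardizing event-related potential (ERP) studies
    collected across acquisition sites. Provides a synthetic multi-site EEG
    generator with known ground truth; harmonization of heterogeneous
    recordings to a canonical sampling rate, montage, reference, bandwidth
    and event matrix, including stimulus-marker timing-delay estimation and
    correction; a seven-step epoch-cleaning pipeline (artifact rejection,
    filtering, ICA-based component removal, spherical-spline channel
    interpolation) with a complete, replayable provenance log and per-step
    archive; adjacency-based cluster permutation statistics with
    cluster-size, cluster-maximum and cluster-mass measures and a
    threshold-free averaged cluster estimate; record-wise versus subject-wise
    cross-validation auditing; and pre-sharing quality-control checks with
    machine-readable reports. Reads and writes European Data Format (EDF/EDF+)
    files and plain-text event, montage and feature tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'cluster-stats.R'
    'epochs.R'
    'harmonize.R'
    'ica.R'
    'interpolate.R'
    'io-edf.R'
    'io-tables.R'
    'ml-validation.R'
    'mseeg-package.R'
    'pipeline.R'
    'qc.R'
    'synthetic.R'
    'utils.R'
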