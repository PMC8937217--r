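Package: axonca
Title: Trial-Aligned Analysis of Two-Photon Calcium Imaging in Go/No-Go Behavior
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing two-photon calcium imaging of axonal
    projections recorded while head-fixed mice perform tactile go/no-go
    tasks. Provides rigid motion correction by whole-frame cross-correlation,
    ROI trace extraction, rolling-median baseline (F0) estimation and
    delta-F/F conversion, threshold-based transient detection with
    amplitude and duration measurement, deduplication of ROIs that are
    branches of the same axon, per-epoch event statistics (probability per
    trial, evoked amplitude and duration) split by behavioral outcome,
    signal-detection behavioral metrics (d-prime, correct fraction, lick
    latency), and trial-aligned pupillometry. A synthetic-session generator
    with full ground truth makes every stage testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
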