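Package: hgparcel
Title: Individual-Level Parcellation of Heschl's Gyrus from Structural
    Connectivity Fingerprints
Version: 0.1.0
Authors@R:
    person("HG", "Parcel Developers", email = "hgparcel@example.org",
           role = c("aut", "cre"))
Description: Connectivity-based parcellation of the human auditory cortex
    (Heschl's gyrus, HG) from diffusion-tractography fingerprints, with
    downstream structural and functional profiling.  Provides a synthetic
    cohort generator emulating the statistical structure of
    high-resolution multimodal MRI inputs (streamline-count fingerprints
    over 42 intrahemispheric targets, resting-state time series with a
    planted medial-to-lateral connectivity axis, and subregion-ordered
    morphometry), K-means clustering with Kneedle elbow selection of the
    number of subregions, soft-thresholded functional connectivity
    profiles, paired-test subregion contrasts with Benjamini-Hochberg
    false-discovery-rate control, and seed-based functional gradient
    mapping with Procrustes alignment to a group reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
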