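Package: thalamloc
Title: Sensory Thalamic Localizer fMRI Analysis with a Synthetic Phantom
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for localizing auditory (medial geniculate, MGN) and
    visual (lateral geniculate, LGN) thalamic nuclei from a clustered-sparse
    functional localizer fMRI task, and for validating the resulting
    functional regions of interest with resting-state functional
    connectivity.  Implements the full analysis chain: clustered-sparse
    trial scheduling, sparse-acquisition design matrices with per-voxel
    ordinary least squares, auditory/visual cortex cluster selection,
    thalamic search-region mask algebra, partial-correlation coactivation
    mapping with size-adaptive thresholds, volume censoring (low-pass
    filtered framewise displacement, GEV-DV signal fluctuation, eye
    closure), and ROI-pair partial-correlation connectivity with
    selectivity contrasts.  A synthetic phantom generator produces labeled
    anatomy, task and resting-state BOLD, motion traces and eye-closure
    logs with the statistical structure the analysis assumes, so every
    stage can be run and verified without scanner data.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
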