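Package: twdfc
Title: Track-Weighted Dynamic Functional Connectivity Mapping and
    Structure-Function Parcellation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Computes track-weighted dynamic functional connectivity
    (TW-dFC) maps from a seed-restricted tractogram and resting-state BOLD
    fMRI: sliding-window endpoint correlations with a Hamming taper are
    projected onto the voxels each streamline traverses and averaged into
    a 4D map.  Includes TCK tractogram and NIfTI input/output, volumetric
    Gaussian smoothing and temporal bandpass filtering, streamline
    endpoint classification and endpoint-density mapping, ICA plus
    k-means parcellation of the seed region from temporally concatenated
    TW-dFC data with bilateral cluster merging, seed-based functional
    connectivity group contrasts with false discovery rate control, and a
    synthetic phantom generator (planted subregions, wired streamlines,
    state-switching BOLD coupling) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    clue,
    ica,
    mclust,
    RNifti,
    signal,
    stats,
    utils
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
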