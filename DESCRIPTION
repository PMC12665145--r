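Package: calpipe
Title: Automated Detection of Spontaneous Calcium Signaling Events in
    Two-Channel Time-Lapse Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-processing pipeline for unbiased detection of
    spontaneous calcium signaling events in two-channel time-lapse
    microscopy of Drosophila lymph gland prohemocytes, where a red
    nuclear marker identifies and tracks cells and a green intensiometric
    calcium biosensor reports activity.  Provides photobleaching
    correction by exponential fitting, frame block averaging,
    Laplacian-of-Gaussian nucleus detection with overlap-based tracking,
    label-mask trace extraction with background correction, iterative
    polynomial baseline estimation, threshold-based event calling with
    duration statistics, and control-based false-discovery-rate
    estimation.  A ground-truthed synthetic movie generator emulating
    drifting nuclei, log-normal expression heterogeneity, boxcar calcium
    transients, photobleaching and pixel noise supports end-to-end
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
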