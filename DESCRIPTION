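Package: renalsync
Title: Synchronization Analysis of Renal Microcirculatory Blood Flow
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for synchronization of tubuloglomerular
    feedback (TGF) oscillations in renal microcirculation imaged with
    laser speckle contrast imaging (LSCI). Covers marker-based frame
    registration, windowed temporal speckle contrast and blood flow index
    (BFI = 1/K^2) computation, adaptive-threshold vessel segmentation,
    continuous wavelet (generalized Morse) tracking of the dominant
    TGF-band frequency and phase on a fixed log-spaced frequency grid,
    frequency-locking synchronization statistics (synchronization degree,
    cluster-membership probability, locking-run durations, distance and
    phase-difference statistics), and plane phase-wave fitting over
    frequency-locked clusters. A synthetic-data module generates
    ground-truthed scenes (BFI movies and speckle-like frame stacks with
    fiducial marker and motion) so that every stage is verifiable against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ape,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
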