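Package: cortexwave
Title: Phase Velocity Field Analysis of Cortex-Wide Propagating Waves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for propagating-wave dynamics in wide-field
    voltage-imaging movies of cortex. Estimates per-pixel phase velocity
    fields from instantaneous oscillation phase by variational optical flow,
    detects and classifies wave patterns (plane waves, standing waves, and
    the local singular patterns source, sink and saddle) via Jacobian
    analysis and Poincare-index bookkeeping, decomposes velocity-field
    sequences into principal spatial modes by singular value decomposition,
    and relates the spatial distribution of local wave patterns to a
    cortical hierarchy index with permutation-null inference. Includes a
    synthetic movie generator (traveling, standing, radial, spiral and
    saddle wave templates plus spectrum-preserving temporal and spatial
    shuffling nulls) so the full pipeline is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'cortexwave-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'synthgen.R'
    'preprocess.R'
    'flow.R'
    'patterns.R'
    'critical.R'
    'tracks.R'
    'modes.R'
    'stats.R'
    'io.R'
    'pipeline.R'
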