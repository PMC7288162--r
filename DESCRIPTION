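Package: emvault
Title: Desk-Scale Storage and Retrieval Engine for Serial-Section EM Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained storage engine for serial-section electron
    microscopy image volumes and contour-based segmentation results.
    Layers are split into fixed-size tiles and stored as a multiresolution
    pyramid under spatial string keys, so any browse viewport resolves to a
    constant number of point lookups. Segmentation contours ("primitives")
    are stored block-duplicated for prefix-scan 2D retrieval and
    value-filter 3D object assembly. A client-side three-level tile cache
    (memory, disk, remote) with direction-aware prefetch and distance-based
    eviction keeps interactive browsing responsive. A deterministic
    synthetic-data generator produces EM-like image stacks and labeled
    object stacks so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    png,
    jpeg,
    tiff,
    yaml,
    optparse,
    EBImage,
    mgcv
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'codec.R'
    'cache.R'
    'cli.R'
    'emvault-package.R'
    'kv-backend.R'
    'segmentation.R'
    'spatial-index.R'
    'synthetic.R'
    'tile-store.R'
    'utils.R'
    'volume-model.R'
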