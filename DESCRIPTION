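Package: thalint
Title: Atlas Registration, Cell Mapping, and Multi-Site Photometry
    Integration for Motor Thalamus Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying convergence of basal ganglia and
    cerebellar signals in the motor thalamus. Registers annotated serial
    coronal sections to a reference atlas through a fiducial and bounding-box
    based chain of affine transforms, maps labeled neurons into atlas space
    and summarizes their regional distribution and 3D density. Preprocesses
    multi-site fiber photometry (background subtraction, low-pass filtering,
    isosbestic dF/F correction), fits a linear integration model testing
    whether thalamic calcium activity is predicted by substantia nigra pars
    reticulata and deep cerebellar nuclei activity against a time-shift
    shuffle null, and quantifies lever-push, locomotion, optogenetic-window
    and evoked-current events. Ships seeded synthetic-data generators for
    every input class so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    signal,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
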