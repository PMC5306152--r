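Package: lfpsim
Title: Ground-Truth Extracellular Potential Synthesis for a Layered
    Cortical Column
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generates Kirchhoff-consistent compartmental activity for a
    14-population thalamocortical column model, stores it in the NSDF
    (Neuroscience Simulation Data Format) HDF5 layout with Dimension
    Scales, and computes simulated extracellular potentials and local
    field potentials (LFP) at arbitrary electrode arrays via the
    point-source forward model, including per-population and
    per-current-type contribution decomposition. Intended as a
    ground-truth benchmark generator for validating analyses of
    multielectrode recordings (CSD estimation, component decomposition,
    spike/LFP studies).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    rhdf5,
    signal,
    pracma,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rhdf5lib
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
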