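Package: embryovision
Title: Video Phenomics of Aquatic Embryos: Segmentation, Spectral Proxy
    Traits, Cardiac Ontogeny and Lethal End Points
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting phenomic measures from time-lapse
    dark-field video of developing aquatic embryos (e.g. the pond snail
    Radix balthica and the amphipod Orchestia gammarellus). From
    per-embryo image sequences the package locates the egg capsule,
    segments the embryo in every frame, derives multiresolution
    blockwise mean-intensity signals and their Welch power spectra,
    integrates per-frame measures into per-timepoint traits (size,
    movement, frequency-band energies), estimates cardiac rate from the
    block spectra and fits linear or segmented ontogeny models, and
    detects lethal end points (osmotic area spikes, spectral-energy
    collapse) with cohort LT25/50/75 survival summaries. A seeded
    synthetic embryo-video generator with full ground truth supports
    validation of every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    jsonlite,
    yaml,
    data.table,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
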