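Package: synstereo
Title: Stereology and 3D Spatial Statistics of Cortical Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of synaptic organization in volume
    electron microscopy data: synapse density estimation with unbiased 3D
    counting frames and artifact-volume correction, tissue shrinkage
    corrections, synaptic apposition surface (SAS) size analysis with
    log-normal maximum-likelihood fits, 3D spatial point-pattern statistics
    (F, G and K functions with complete-spatial-randomness simulation
    envelopes), Cavalieri point-count volume fractions, and the
    nonparametric group-comparison conventions used in cortical synapse
    studies. Includes a calibrated synthetic neuropil generator so the whole
    pipeline can be exercised and validated without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
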