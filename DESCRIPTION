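Package: nectarct
Title: Micro-CT Phenotyping of Nectar-Related Floral Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies nectar-related floral traits from volumetric X-ray
    micro-computed tomography image stacks. Segments the nectary gland from
    reconstructed greyscale slices (tissue/air thresholding, topographic
    height projection, watershed compartmentalization, harmonic
    interpolation of the hidden lower surface), measures gland volume and
    air-contact surface area, reconstructs the nectar level inside the
    corolla from a capillary-measured nectar volume, computes flower width
    and virtual longitudinal cross-section areas, runs the
    Shapiro/Levene/t-test group-comparison procedure and linear
    regression/correlation over per-flower measurement records, and models
    honey-bee head accessibility by rigid superposition. A synthetic
    flower-phantom generator with analytic ground truth supports validation
    of every stage without real scans.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tiff,
    png,
    jsonlite,
    EBImage,
    Matrix,
    car,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
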