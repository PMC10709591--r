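Package: vtsct
Title: Virtual Thin-Section CT Simulation, Reconstruction and Agreement Analysis for Lung Nodule Solid-Size Measurement
Version: 0.1.0
Authors@R: person("Shingo", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for studying through-plane super-resolution of chest CT at
    phantom scale. Generates seeded three-dimensional lung-nodule phantoms
    (solid, part-solid and pure ground-glass) with exact ground truth,
    simulates conventional thick-slice CT from thin-section volumes by slab
    averaging, trains a compact conditional adversarial slice-interpolation
    model that reconstructs virtual thin sections from thick slices, measures
    maximal solid and total nodule size on axial, coronal and sagittal
    multiplanar reconstructions, assigns clinical T categories from solid
    size, and computes the inter-observer agreement battery (intraclass
    correlation, Cohen's kappa with confidence bands, dependent-correlation
    comparison, analysis of covariance). Includes an end-to-end study harness
    reproducing the validation design at phantom scale, MetaImage and NIfTI-1
    volume input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    igraph,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
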