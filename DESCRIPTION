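Package: npfate
Title: Correlative X-Ray Imaging Analysis of Nanoparticle Fate in Plant Leaves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for tracking the fate of foliar-applied nanoparticles in
    plant tissue from three complementary X-ray modalities. Reduces scanning
    small-angle X-ray scattering (SAXS) mesh scans to caked I(q, theta),
    radial and azimuthal profiles, and assembles total-scattering and
    first-moment anisotropy maps; fits the Guinier approximation to solution
    scattering curves and analyses dilution series; quantifies
    nanoparticle-densified regions in reconstructed micro-CT volumes by
    semi-automated threshold segmentation; compares X-ray fluorescence
    element maps against a control reference; and classifies the joint
    SAXS/CT/XRF signal trends into aggregation, dispersion, dissolution or
    translocation. A synthetic phantom generator with analytic nanoparticle
    form factors and an oriented cellulose background makes the whole
    pipeline testable without beamline data. Includes an X-ray dose
    calculator and cone-beam geometry helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    pracma,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
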