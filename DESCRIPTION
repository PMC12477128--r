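Package: wallstrain
Title: Ultrasound Elastography of Arterial Wall Strain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates aortic wall deformation over one cardiac cycle from
    cross-sectional cine image loops. A four-node quadrilateral finite-element
    mesh is placed over a two-contour wall region of interest, nodal
    displacements are tracked frame to frame by regularized non-rigid
    intensity registration, and per-element Green-Lagrange strain yields the
    peak mean tensile principal wall strain normalized by brachial pulse
    pressure (percent per mmHg), a stiffness surrogate for abdominal aortic
    aneurysm surveillance. Includes a speckle phantom generator with analytic
    ground-truth displacement and strain, parametric strain imaging,
    outer-wall caliper diameter measurement, and longitudinal cohort tools
    (visit pairing, tercile stratification at fixed cutoffs, annualized
    change rates, and nonparametric group comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    tiff,
    png,
    stats,
    grDevices,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
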