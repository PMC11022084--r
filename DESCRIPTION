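Package: lamcoord
Title: Laminar and Equivolumetric Coordinate Systems Between Cortical Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds laminar ("normal") coordinate systems for the space between
    two triangulated surfaces, such as the grey-white and pial boundaries of a
    cortical area. Surfaces are registered by a kernel-based diffeomorphic
    (LDDMM) flow with a varifold matching term, optionally subject to a
    streamline-normality constraint solved by an augmented Lagrangian method.
    The resulting streamlines carry thickness, surface-Jacobian, and
    equivolumetric-depth fields, and layers are reparametrized to satisfy a
    localized equivolumetric (Bok) condition. Includes synthetic phantom
    generators with analytic ground truth, mesh I/O (OFF, PLY, VTK legacy
    polydata), discrete differential-geometry operators, and validation
    metrics (FreeSurfer-style vertex distances, area-evolution residuals,
    equivolume checks).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
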