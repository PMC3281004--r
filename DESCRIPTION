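Package: furrowbend
Title: Cortical Bending Stiffness Estimation from Dividing-Cell Shapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward and inverse mechanics of cytokinetic cell shape under
    a Helfrich-type bending energy. Computes minimum-bending-energy
    axisymmetric surfaces under cell volume and surface area constraints
    with a spatially varying bending modulus Kc(s) and a contractile-ring
    line tension, estimates Kc(s) from observed contours by regularized
    quasi-Newton fitting, quantifies cell contours and discrete curvatures
    from membrane-labeled fluorescence images, and generates ground-truthed
    synthetic dividing-cell data (contours, observations, rendered images)
    for validation and in-silico experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    minpack.lm,
    jsonlite,
    png,
    tiff
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
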