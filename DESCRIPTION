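Package: npsim
Title: Material Point Method Simulation of Nucleus-Pulposus-Like Soft Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A moving-least-squares material point method (MLS-MPM) solver for
    simulating soft, viscoelastic-plastic tissue such as the nucleus pulposus of
    the intervertebral disc during clamping procedures. Implements a
    Neo-Hookean constitutive model with a multiplicative elastic-plastic split
    of the deformation gradient, volume-ratio limits that produce creep and
    stress relaxation, hardened Lame coefficients, an affine (APIC) transfer
    loop on a regular background grid, a rigid two-box clamp with particle
    capture and impulse-based force output for haptic devices, and scripted
    tear, creep, and stress-relaxation characterization experiments with
    stress-strain curve extraction and stage segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
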