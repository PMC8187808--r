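Package: osteofa
Title: Bilateral Asymmetry Analysis of Developing Long Bones
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Measures humeral length and midshaft cortical thickness from
    paired left/right 3D bone surface models (STL), estimates signed and
    size-corrected bilateral asymmetry, classifies fluctuating versus
    directional asymmetry versus antisymmetry, computes the FA6
    developmental-instability index, and analyses stage-wise asymmetry
    trajectories across prenatal development. Includes a synthetic-data
    generator producing paired-trait tables and watertight bone meshes
    with known asymmetry structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
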